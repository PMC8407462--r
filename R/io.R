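#' Read an ASV count table from TSV
#'
#' Reads a tab-separated count table with samples as rows (first column:
#' sample identifiers) and ASVs as columns (header row: ASV identifiers).
#' Samples whose total read count does not exceed `min_reads` are dropped,
#' mirroring the usual amplicon quality gate of requiring more than 10,000
#' reads per sample; the number of dropped samples is reported via
#' `message()`.
#'
#' @param path Path to a TSV file.
#' @param min_reads Minimum library size; samples with total reads
#'   `<= min_reads` are removed. Set to `0` to keep everything.
#' @return Integer matrix (samples x ASVs) with dimnames.
#' @export
read_count_table <- function(path, min_reads = 10000) {
  if (!file.exists(path)) stop("count table not found: ", path)
  if (file.size(path) == 0) stop("count table is empty: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  if (ncol(df) < 2) stop("count table needs a sample id column and at least one ASV column")
  sample_ids <- as.character(df[[1]])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1])
  asv_ids <- colnames(df)[-1]
  if (anyDuplicated(asv_ids))
    stop("duplicate ASV id: ", asv_ids[duplicated(asv_ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-integer cell in column '", asv_ids[bad], "'")
  }
  if (any(m < 0) || any(m != round(m))) {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)[1, ]
    stop("non-integer or negative count at row '", sample_ids[bad[1]],
         "', column '", asv_ids[bad[2]], "'")
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(sample_ids, asv_ids)
  keep <- rowSums(m) > min_reads
  if (any(!keep))
    message(sum(!keep), " sample(s) dropped with <= ", min_reads, " reads")
  m[keep, , drop = FALSE]
}

#' Write an ASV count table to TSV
#'
#' @param counts Integer matrix (samples x ASVs) with dimnames.
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a taxonomy table
#'
#' Taxonomy tables are TSV with columns `asv_id`, `kingdom`, `phylum`,
#' `class`, `order`, `family`, `genus`, `species`; unassigned ranks are
#' empty strings.
#'
#' @param path File path.
#' @return Data frame of rank assignments.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "", na.strings = NULL)
  need <- c("asv_id", "kingdom", "phylum", "class", "order", "family",
            "genus", "species")
  if (!all(need %in% colnames(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$asv_id)) stop("duplicate asv_id in taxonomy table")
  df
}

#' @rdname read_taxonomy
#' @param tax Taxonomy data frame.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' @param path File path.
#' @return Data frame, one row per sample, first column `sample_id`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  if (colnames(df)[1] != "sample_id") stop("metadata must start with a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df
}

#' @rdname read_metadata
#' @param meta Metadata data frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labelled square distance matrix
#'
#' @param path File path.
#' @return Symmetric numeric matrix with matching dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must be square with matching labels")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  m
}

#' @rdname read_distance_matrix
#' @param d Symmetric matrix.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse Greengenes-style taxonomy strings
#'
#' Converts rank strings such as
#' `"k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales;
#' f__Bacteroidaceae; g__Bacteroides; s__uniformis"` into the columnar
#' taxonomy layout used throughout the package. Missing or empty ranks
#' (e.g. a bare `"s__"`) become empty strings; a species entry that
#' does not already contain the genus name is prefixed with it.
#'
#' @param asv_ids ASV identifiers.
#' @param strings Greengenes-style rank strings, one per ASV.
#' @return Taxonomy data frame (see [read_taxonomy()]).
#' @export
parse_greengenes <- function(asv_ids, strings) {
  stopifnot(length(asv_ids) == length(strings))
  prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                family = "f", genus = "g", species = "s")
  out <- data.frame(asv_id = asv_ids, stringsAsFactors = FALSE)
  parts <- strsplit(strings, ";\\s*")
  for (rank in names(prefixes)) {
    pat <- paste0("^", prefixes[[rank]], "__")
    out[[rank]] <- vapply(parts, function(p) {
      hit <- grep(pat, p, value = TRUE)
      if (length(hit) == 0) "" else sub(pat, "", hit[[1]])
    }, character(1))
  }
  sp <- nzchar(out$species) & nzchar(out$genus) &
    !startsWith(out$species, out$genus)
  out$species[sp] <- paste(out$genus[sp], out$species[sp])
  out
}

#' Lowest assigned taxon of each ASV
#'
#' @param tax Taxonomy data frame (see [read_taxonomy()]).
#' @return Character vector named by `asv_id`: the deepest non-empty rank
#'   label of each ASV.
#' @export
lowest_taxon <- function(tax) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  out <- apply(as.matrix(tax[, ranks]), 1, function(r) {
    r <- r[!is.na(r) & nzchar(r)]
    if (length(r) == 0) "Unassigned" else r[[length(r)]]
  })
  names(out) <- tax$asv_id
  out
}

#' Assign human-readable display names to ASVs
#'
#' ASVs are named after their lowest assigned taxonomy label plus their
#' rank by total read count among ASVs sharing that label, e.g. the most
#' abundant ASV classified as Faecalibacterium prausnitzii becomes
#' `"Faecalibacterium prausnitzii ASV 1"`. Ties in total count are broken
#' by lexicographic ASV id.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param tax Taxonomy data frame covering every ASV in `counts`.
#' @return `tax` with columns `lowest_taxon` and `display_name` added.
#' @export
assign_display_names <- function(counts, tax) {
  missing <- setdiff(colnames(counts), tax$asv_id)
  if (length(missing))
    stop("taxonomy missing for ASV(s): ", paste(utils::head(missing, 3), collapse = ", "))
  tax <- tax[match(colnames(counts), tax$asv_id), , drop = FALSE]
  low <- lowest_taxon(tax)
  tot <- colSums(counts)
  ord <- order(low, -tot, tax$asv_id)
  rank_in_group <- stats::ave(seq_along(ord), low[ord], FUN = seq_along)
  display <- character(length(ord))
  display[ord] <- paste0(low[ord], " ASV ", rank_in_group)
  tax$lowest_taxon <- unname(low)
  tax$display_name <- display
  rownames(tax) <- NULL
  tax
}

#' Export an association network
#'
#' Writes the dual-criterion ASV network either as GraphML (for external
#' viewers) or as a plain edge-list TSV. Nodes carry prevalence, total
#' count, phylum and cluster id; edges carry the Spearman rho and both
#' q-values.
#'
#' @param net An `gut_network` object from [build_network()].
#' @param clusters Optional cluster data frame from [find_clusters()];
#'   used to annotate nodes with their cluster id.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
export_network <- function(net, clusters = NULL, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  nodes <- net$nodes
  nodes$cluster <- NA_character_
  if (!is.null(clusters) && nrow(clusters))
    nodes$cluster[match(clusters$member, nodes$asv_id)] <- clusters$cluster
  if (format == "edgelist") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(net$edges)) net$edges[, c("asv_a", "asv_b")] else
      data.frame(asv_a = character(), asv_b = character()),
    directed = FALSE,
    vertices = nodes[, c("asv_id", "prevalence", "total_count", "phylum", "cluster")])
  if (nrow(net$edges)) {
    igraph::E(g)$rho <- net$edges$rho
    igraph::E(g)$fisher_q <- net$edges$fisher_q
    igraph::E(g)$rho_q <- net$edges$rho_q
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read back an exported edge list
#'
#' @param path Edge-list TSV written by [export_network()].
#' @return Data frame of edges.
#' @export
read_edge_list <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
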