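# Plain-text readers/writers for all pipeline artifacts. Every writer
# produces a deterministic column order so reruns are checksum-identical.

#' Write / read a marker matrix as TSV
#'
#' First column `line_id`, then one 0/1 column per marker.
#' @param markers lines x markers matrix with rownames.
#' @param path output file.
#' @export
write_marker_tsv <- function(markers, path) {
  df <- data.frame(line_id = rownames(markers), markers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$line_id
  m
}

#' Write / read plot-level phenotypes as TSV
#'
#' Columns `year management trial rep block line_id GY AD PH`.
#' @param pheno phenotype data.frame.
#' @param path output file.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  cols <- c("year", "management", "trial", "rep", "block", "line_id",
            intersect(c("GY", "AD", "PH"), names(pheno)))
  utils::write.table(pheno[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(year = "character"))
}

#' Write / read a genomic relationship matrix as TSV
#'
#' Line ids as header row and first column.
#' @param G a `grm` (or plain matrix with dimnames).
#' @param path output file.
#' @export
write_grm_tsv <- function(G, path) {
  df <- data.frame(line_id = rownames(G), unclass(G),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  dimnames(G) <- list(df$line_id, df$line_id)
  structure(G, m = NA_integer_, class = c("grm", "matrix", "array"))
}

#' Write / read the long-format BLUE table as TSV
#' @param blues BLUE data.frame from [stage1_blues()].
#' @param path output file.
#' @export
write_blues_tsv <- function(blues, path) {
  cols <- c("line_id", "year", "management", "trait", "blue", "se")
  utils::write.table(blues[, intersect(cols, names(blues))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blues_tsv
#' @export
read_blues_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(year = "character"))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain `seed`, `stages`, a `sim` block of [sim_config()]
#' overrides, `maf_threshold`, optional `inputs` paths (pre-existing marker /
#' phenotype TSVs) and a `cv` block (scenario list, `fractions`, `reps`,
#' `traits`, `managements`, `method`).
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}
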