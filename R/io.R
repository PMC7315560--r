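# Delimited-text I/O for beta matrices, sample metadata and probe sets.

#' Beta-value matrix with sample metadata
#'
#' The carrier object for DNAm data: a probes-by-samples matrix of beta
#' values in `[0, 1]` (missing values allowed) plus a per-sample metadata
#' `data.frame` with at least `sample_id` and `age` (years).
#'
#' @param betas Numeric matrix, probes as rows with unique row names,
#'   samples as columns with unique column names.
#' @param samples `data.frame` with columns `sample_id` (matching the matrix
#'   columns) and `age`; extra columns (group, tissue, ...) are kept.
#' @return An object of class `beta_matrix`: list with `betas` and
#'   `samples` (rows aligned to matrix columns).
#' @examples
#' m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' beta_matrix(m, data.frame(sample_id = c("s1", "s2"), age = c(30, 60)))
#' @export
beta_matrix <- function(betas, samples) {
  stopifnot(is.matrix(betas), is.data.frame(samples),
            all(c("sample_id", "age") %in% names(samples)))
  if (is.null(rownames(betas)) || anyDuplicated(rownames(betas))) {
    stop("probe ids (row names) must be present and unique")
  }
  if (is.null(colnames(betas)) || anyDuplicated(colnames(betas))) {
    stop("sample ids (column names) must be present and unique")
  }
  if (any(betas < 0 | betas > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  samples <- samples[match(colnames(betas), samples$sample_id), ,
                     drop = FALSE]
  if (any(is.na(samples$sample_id))) {
    stop("every matrix sample must appear in the metadata")
  }
  if (any(!is.na(samples$age) & samples$age <= 0)) {
    stop("ages must be positive where present")
  }
  rownames(samples) <- NULL
  structure(list(betas = betas, samples = samples), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples, ages %.1f-%.1f years\n",
              nrow(x$betas), ncol(x$betas),
              min(x$samples$age, na.rm = TRUE),
              max(x$samples$age, na.rm = TRUE)))
  invisible(x)
}

#' @rdname beta_matrix
#' @param sim A `simulated_cohort` from [simulate_cohort()].
#' @export
as_beta_matrix <- function(sim) {
  stopifnot(inherits(sim, "simulated_cohort"))
  beta_matrix(sim$betas,
              data.frame(sample_id = names(sim$ages), age = unname(sim$ages),
                         stringsAsFactors = FALSE))
}

# Tab if the first line contains one, else comma.
.sniff_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

.na_strings <- c("NA", "na", "Na", "nA", "")

#' Read a beta matrix and sample metadata from delimited text
#'
#' The matrix file has probes as rows (first column probe ids), a header row
#' of sample ids, and tab- or comma-separated numeric beta values; the
#' metadata file has at least `sample_id` and `age` columns. Values outside
#' `[0, 1]` by at most `1e-6` are clamped; larger violations are an error.
#' Matrix samples missing from the metadata are dropped with a warning.
#' Missing values may be written as `NA` (any case) or left empty.
#'
#' @param path Matrix file.
#' @param metadata_path Metadata file.
#' @param sep Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   per file.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, metadata_path, sep = NULL) {
  msep <- if (is.null(sep)) .sniff_sep(path) else sep
  raw <- utils::read.table(path, header = TRUE, sep = msep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = .na_strings, comment.char = "")
  if (ncol(raw) < 2) stop("matrix file needs a probe_id column plus samples")
  probe_ids <- as.character(raw[[1]])
  if (anyDuplicated(probe_ids)) {
    stop(sprintf("duplicate probe ids, e.g. %s",
                 probe_ids[duplicated(probe_ids)][1]))
  }
  vals <- raw[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    stop(sprintf("non-numeric beta values in column(s): %s",
                 paste(names(vals)[nonnum], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- probe_ids
  out_of_range <- !is.na(m) & (m < -1e-6 | m > 1 + 1e-6)
  if (any(out_of_range)) {
    stop(sprintf("%d beta value(s) outside [0, 1] beyond tolerance 1e-6",
                 sum(out_of_range)))
  }
  m <- pmin(pmax(m, 0), 1)
  ssep <- if (is.null(sep)) .sniff_sep(metadata_path) else sep
  meta <- utils::read.table(metadata_path, header = TRUE, sep = ssep,
                            stringsAsFactors = FALSE,
                            na.strings = .na_strings)
  if (!all(c("sample_id", "age") %in% names(meta))) {
    stop("metadata needs `sample_id` and `age` columns")
  }
  meta$sample_id <- as.character(meta$sample_id)
  common <- intersect(colnames(m), meta$sample_id)
  if (length(common) == 0) {
    stop("no overlap between matrix samples and metadata sample ids")
  }
  dropped <- setdiff(colnames(m), common)
  if (length(dropped) > 0) {
    warning(sprintf("%d matrix sample(s) absent from metadata dropped: %s%s",
                    length(dropped),
                    paste(utils::head(dropped, 3), collapse = ", "),
                    if (length(dropped) > 3) ", ..." else ""))
    m <- m[, common, drop = FALSE]
  }
  beta_matrix(m, meta)
}

#' Write a beta matrix and its metadata to delimited text
#'
#' @param bm A [beta_matrix()].
#' @param path Matrix output file.
#' @param metadata_path Metadata output file.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path, metadata_path, sep = "\t") {
  stopifnot(inherits(bm, "beta_matrix"))
  df <- data.frame(probe_id = rownames(bm$betas), bm$betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(bm$samples, metadata_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a probe set, optionally with per-probe clock parameters
#'
#' Accepts either a bare list (one probe id per line, no header) or a
#' delimited file with a `probe_id` header and optional `delta` / `beta0`
#' columns (a clock parameter table, including the files
#' [write_parameter_table()] emits). Lines starting with `#` are ignored.
#'
#' @param path Input file.
#' @param sep Delimiter for the tabular form; `NULL` auto-detects.
#' @return For a bare list, a character vector of probe ids; for the
#'   tabular form, a `data.frame` with `probe_id` and any parameter columns.
#' @export
load_probe_set <- function(path, sep = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop("no content in probe-set file")
  tabular <- grepl("probe_id", lines[1], fixed = TRUE)
  if (!tabular) {
    probes <- trimws(lines)
    probes <- probes[probes != ""]
    if (anyDuplicated(probes)) {
      stop(sprintf("duplicate probe id: %s", probes[duplicated(probes)][1]))
    }
    return(probes)
  }
  if (is.null(sep)) sep <- if (grepl("\t", lines[1])) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = .na_strings)
  tab$probe_id <- as.character(tab$probe_id)
  if (anyDuplicated(tab$probe_id)) {
    stop(sprintf("duplicate probe id: %s",
                 tab$probe_id[duplicated(tab$probe_id)][1]))
  }
  for (col in intersect(c("delta", "beta0"), names(tab))) {
    if (!is.numeric(tab[[col]])) {
      stop(sprintf("column `%s` must be numeric", col))
    }
  }
  tab
}

#' Write a simulated cohort to disk
#'
#' Emits the beta matrix and metadata in the same text format
#' [read_beta_matrix()] reads, plus a truth table (`probe_id`, `true_delta`,
#' `true_beta0`, `true_ir`) and the generating spec as plain `key = value`
#' lines.
#'
#' @param sim A `simulated_cohort`.
#' @param prefix Output path prefix; files `<prefix>_betas.tsv`,
#'   `_metadata.tsv`, `_truth.tsv`, `_spec.txt` are written.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(sim, prefix) {
  stopifnot(inherits(sim, "simulated_cohort"))
  paths <- c(betas = paste0(prefix, "_betas.tsv"),
             metadata = paste0(prefix, "_metadata.tsv"),
             truth = paste0(prefix, "_truth.tsv"),
             spec = paste0(prefix, "_spec.txt"))
  write_beta_matrix(as_beta_matrix(sim), paths["betas"], paths["metadata"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- sim$spec
  writeLines(c(
    sprintf("n_sites = %d", s$n_sites),
    sprintf("n_samples = %d", s$n_samples),
    sprintf("true_ir = %.15g", s$true_ir),
    sprintf("beta0 = %.15g", s$beta0),
    sprintf("delta_pool = %s", paste(s$delta_pool, collapse = ",")),
    sprintf("age_range = %s", paste(s$age_range, collapse = ",")),
    sprintf("seed = %d", s$seed),
    sprintf("direction = %s", s$direction),
    sprintf("delta_assignment = %s", s$delta_assignment)
  ), paths["spec"])
  invisible(paths)
}
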