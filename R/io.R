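#' Read correlation triplets from a CSV or JSON file
#'
#' The file must provide columns (or JSON fields) \code{r1y}, \code{r2y},
#' \code{r12} and \code{n}; an optional \code{label} column is carried
#' through. Every record is validated; an out-of-range correlation or
#' undersized \code{n} raises an error naming the offending row.
#'
#' @param path path to a \code{.csv} or \code{.json} file.
#' @return a list of records, each a list with \code{label} and
#'   \code{triplet} (a [cor_triplet()]).
#' @seealso [write_results()] for the output side.
#' @export
read_triplets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("r1y", "r2y", "r12", "n")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    tr <- tryCatch(
      cor_triplet(d$r1y[i], d$r2y[i], d$r12[i], d$n[i]),
      error = function(e)
        stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE))
    list(label = if ("label" %in% names(d)) as.character(d$label[i])
                 else sprintf("record_%d", i),
         triplet = tr)
  })
}

#' Run the tests over a batch of triplets
#'
#' @param records a list as returned by [read_triplets()], or a single
#'   [cor_triplet()].
#' @inheritParams dep_cor_test_all
#' @return a data frame with one row per (record, test), including the
#'   input correlations so the output is self-describing and re-readable.
#' @export
run_batch <- function(records, tests = .test_names(), alpha = 0.05,
                      cap_f = FALSE) {
  if (inherits(records, "cor_triplet"))
    records <- list(list(label = "record_1", triplet = records))
  rows <- lapply(records, function(rec) {
    res <- dep_cor_test_all(rec$triplet, tests = tests, alpha = alpha,
                            cap_f = cap_f)
    cbind(label = rec$label,
          r1y = rec$triplet$r1y, r2y = rec$triplet$r2y,
          r12 = rec$triplet$r12, n = rec$triplet$n, res)
  })
  do.call(rbind, rows)
}

#' Write a results table to CSV
#'
#' Full numeric precision is retained (15 significant digits) so that a
#' written table re-read with [utils::read.csv()] round-trips.
#'
#' @param results a data frame (e.g. from [run_batch()] or the sweeps).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  num <- vapply(results, is.double, TRUE)
  results[num] <- lapply(results[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, scientific = FALSE,
                                trim = TRUE))
  })
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
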