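# Long-format plot table: CSV with mandatory header
#   site, block, genotype, group, response
# group in {gmo, comparator, reference}; response is log scale. Unknown
# columns are preserved on read but ignored. Responses are written as C
# "%.17g" so a write/read round trip is bit-exact.

#' Write a trial dataset to CSV
#'
#' Deterministic row order (site, then block, then genotype) and
#' full-precision decimal rendering, so a round trip through
#' [read_trial_csv()] reproduces every response bit-exactly.
#'
#' @param data A `trial_dataset`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_trial_csv <- function(data, path) {
  design <- attr(data, "design")
  if (is.null(design)) design <- .design_from_records(data)
  gi <- match(data$genotype, design$genotypes$label)
  ord <- order(data$site, data$block, gi)
  out <- as.data.frame(data)[ord, c("site", "block", "genotype", "group", "response")]
  out$response <- sprintf("%.17g", out$response)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a trial dataset from CSV
#'
#' Parses a long-format plot table, validates it (schema columns present,
#' group labels legal, responses numeric and finite, one record per
#' site/block/genotype cell) and returns a `trial_dataset`. Errors cite the
#' offending row (counting the header as line 1) and column.
#'
#' @param path CSV file path.
#' @return A validated `trial_dataset`.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    strip.white = TRUE),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(raw) == 0)
    stop("'", path, "' contains no data rows", call. = FALSE)
  needed <- c("site", "block", "genotype", "group", "response")
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad_grp <- which(!raw$group %in% .groups)
  if (length(bad_grp))
    stop("unknown group label ", dQuote(raw$group[bad_grp[1]]), " in column 'group', ",
         "row ", bad_grp[1] + 1L, " of '", path,
         "' (expected gmo, comparator or reference)", call. = FALSE)
  resp <- suppressWarnings(as.numeric(raw$response))
  bad_num <- which(is.na(resp) | !is.finite(resp))
  if (length(bad_num))
    stop("unparseable or non-finite response ", dQuote(raw$response[bad_num[1]]),
         " in column 'response', row ", bad_num[1] + 1L, " of '", path, "'",
         call. = FALSE)
  rec <- data.frame(site = utils::type.convert(raw$site, as.is = TRUE),
                    block = utils::type.convert(raw$block, as.is = TRUE),
                    genotype = raw$genotype, group = raw$group, response = resp,
                    stringsAsFactors = FALSE)
  trial_dataset(rec, validate = TRUE)
}
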