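# GWAS summary statistics exchanged in the GCTA-COJO ".ma" text format:
# whitespace table with header "SNP A1 A2 freq b se p N".

#' Validate a summary-statistics data frame
#'
#' @param sumstats data.frame with columns `SNP`, `A1`, `A2`, `freq`, `b`,
#'   `se`, `p`, `N`.
#' @return The validated data.frame (invisibly usable downstream).
#' @export
validate_sumstats <- function(sumstats) {
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  miss <- setdiff(need, names(sumstats))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(sumstats$se <= 0)) stop("se must be positive", call. = FALSE)
  if (any(sumstats$p <= 0 | sumstats$p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  if (any(sumstats$N <= 0)) stop("N must be positive", call. = FALSE)
  sumstats[, need]
}

#' Read / write COJO ".ma" summary statistics
#'
#' @param path file path.
#' @return `read_ma()` returns a validated summary-statistics data.frame.
#' @export
read_ma <- function(path) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  validate_sumstats(x)
}

#' @rdname read_ma
#' @param sumstats summary-statistics data.frame (see [validate_sumstats()]).
#' @export
write_ma <- function(sumstats, path) {
  sumstats <- validate_sumstats(sumstats)
  # write.table converts each value independently (15 significant digits),
  # so mixed-magnitude columns keep full printed precision
  utils::write.table(sumstats, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}
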