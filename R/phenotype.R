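#' Germination index from staged germination counts
#'
#' The germination index (GI) of a 6-day germination test weights early
#' germination more heavily than late germination:
#' \deqn{GI = \frac{6 n_3 + 3 n_6}{6 N}}
#' where \eqn{n_3} is the number of seeds germinated by day 3,
#' \eqn{n_6} the number germinated between day 3 and day 6, and \eqn{N}
#' the number of seeds tested. GI lies in \eqn{[0, 1]}; lower values
#' indicate stronger seed dormancy and hence stronger resistance to
#' pre-harvest sprouting.
#'
#' Note that \code{n6} is the *incremental* day-6 count, not the
#' cumulative count: callers holding cumulative day-6 totals must
#' subtract \code{n3} first.
#'
#' @param n3 seeds germinated by day 3 (vectorized).
#' @param n6 seeds germinated between day 3 and day 6.
#' @param N total seeds tested per plot (default 40).
#' @return numeric vector of germination indices in \eqn{[0, 1]}.
#' @export
#' @examples
#' computeGI(10, 10, 40) # (60 + 30) / 240 = 0.375
#' computeGI(40, 0, 40)  # 1
computeGI <- function(n3, n6, N = 40) {
  k <- max(length(n3), length(n6), length(N))
  n3 <- rep_len(n3, k); n6 <- rep_len(n6, k); N <- rep_len(N, k)
  bad <- is.na(n3) | is.na(n6) | is.na(N) | n3 < 0 | n6 < 0 | N < 1 |
    n3 + n6 > N
  if (any(bad))
    stop("invalid germination record(s) at position(s) ",
         paste(which(bad), collapse = ", "),
         ": need n3 >= 0, n6 >= 0, n3 + n6 <= N, N >= 1", call. = FALSE)
  (6 * n3 + 3 * n6) / (6 * N)
}

#' Build the plot-level phenotype table
#'
#' Converts raw plot germination records into GI records, validating the
#' counts and rejecting duplicate (genotype, environment, replicate)
#' keys. Plots tested with other than 40 seeds are accepted (the GI
#' formula generalizes) with a warning.
#'
#' @param plots \code{data.frame} with columns \code{genotype_id},
#'   \code{environment_id}, \code{replicate}, \code{n3}, \code{n6} and
#'   optionally \code{N} (default 40).
#' @return \code{data.frame} with columns \code{genotype_id},
#'   \code{environment_id}, \code{replicate}, \code{gi}.
#' @export
#' @examples
#' plots <- data.frame(genotype_id = "g1", environment_id = "E1",
#'                     replicate = 1:2, n3 = c(10, 40), n6 = c(10, 0))
#' buildPhenotypeTable(plots)
buildPhenotypeTable <- function(plots) {
  need <- c("genotype_id", "environment_id", "replicate", "n3", "n6")
  miss <- setdiff(need, colnames(plots))
  if (length(miss))
    stop("plot table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"N" %in% colnames(plots)) plots$N <- 40L
  key <- paste(plots$genotype_id, plots$environment_id, plots$replicate,
               sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (genotype, environment, replicate) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  if (any(plots$N != 40))
    warning(sum(plots$N != 40),
            " plot(s) tested with N != 40 seeds; GI generalizes but ",
            "precision differs", call. = FALSE)
  gi <- tryCatch(computeGI(plots$n3, plots$n6, plots$N),
                 error = function(e) {
                   stop("invalid plot record(s): ", conditionMessage(e),
                        "; keys: ",
                        paste(head(key, 5), collapse = ", "),
                        call. = FALSE)
                 })
  data.frame(genotype_id = as.character(plots$genotype_id),
             environment_id = as.character(plots$environment_id),
             replicate = plots$replicate, gi = gi,
             stringsAsFactors = FALSE)
}

#' Read a plot germination table from delimited text
#'
#' Comma- or tab-separated, chosen from the file extension (.csv vs
#' .tsv/.txt); expects the columns of [buildPhenotypeTable()].
#'
#' @param path file path.
#' @return \code{data.frame} of plot records.
#' @export
readPlotTable <- function(path) .readDelim(path)
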