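#' Candidate marker pool for multi-marker models
#'
#' Takes the stable markers and collapses complete-LD groups to a
#' single representative (markers in complete LD carry identical
#' information; keeping both would make every subset containing the
#' pair singular).
#'
#' @param stability stability table from [classifyStability()], or a
#'   character vector of stable marker identifiers.
#' @param ldGroups complete-LD groups from [detectCompleteLD()].
#' @return character vector of pool marker identifiers, in input order.
#' @export
candidatePool <- function(stability, ldGroups = list()) {
  stable <- if (is.character(stability)) stability
            else stability$marker_id[stability$stable]
  pool <- stable
  for (grp in ldGroups) {
    members <- intersect(grp$markers, stable)
    if (length(members) < 2) next
    keep <- if (grp$representative %in% members)
      grp$representative else members[1]
    pool <- setdiff(pool, setdiff(members, keep))
  }
  if (!length(pool))
    stop("candidate pool is empty: no stable markers remain")
  pool
}

#' All-subsets regression of across-environment GI BLUPs on markers
#'
#' Fits every non-empty subset of the candidate pool by ordinary least
#' squares on tolerant-allele indicators (1 = homozygous for the
#' tolerant allele, 0 = susceptible class; the orientation is decided
#' per marker from the across-environment class means) and ranks the
#' subsets by the least-squares AIC
#' \deqn{AIC = n \ln(RSS/n) + 2 (k + 1),}
#' \eqn{k} the number of predictors (+1 for the intercept; the constant
#' from the Gaussian likelihood is identical across models and
#' dropped, so only AIC differences are meaningful). Genotypes missing
#' a homozygous call at *any* pool marker are removed once
#' (complete-case over the pool union), so AICs are computed on a
#' common genotype set and comparable across subsets. Singular subsets
#' are skipped with a message. Ties in AIC (below 1e-9) are broken by
#' smaller subset size, then lexicographic marker order.
#'
#' @param blupAcross across-environment BLUP table
#'   (\code{genotype_id}, \code{blup_gi}).
#' @param panel a \linkS4class{MarkerPanel}.
#' @param pool character vector of candidate markers (at most 20).
#' @param kTop number of top models to return (default 10).
#' @return list with \code{models} (a \code{data.frame}: \code{rank},
#'   \code{markers} (comma-joined), \code{size}, one effect column per
#'   pool marker, \code{pve}, \code{aic}), \code{orientation} (named
#'   tolerant allele per pool marker), \code{n} (genotypes used) and
#'   \code{nSubsets} (subsets evaluated).
#' @export
allSubsetsRegression <- function(blupAcross, panel, pool, kTop = 10) {
  p <- length(pool)
  if (p < 1) stop("empty candidate pool")
  if (p > 20) stop("pool of ", p, " markers would need 2^", p,
                   " subsets; restrict the pool to <= 20")
  calls <- markerCalls(panel)[pool, , drop = FALSE]
  calls[.isHet(calls)] <- NA_character_
  a <- matrix(.allele1(calls), nrow = p,
              dimnames = list(pool, colnames(calls)))
  common <- intersect(blupAcross$genotype_id, colnames(a))
  a <- a[, common, drop = FALSE]
  keep <- colSums(is.na(a)) == 0          # complete cases over the pool
  a <- a[, keep, drop = FALSE]
  y <- blupAcross$blup_gi[match(colnames(a), blupAcross$genotype_id)]
  n <- length(y)
  if (n < p + 2) stop("too few complete-case genotypes (", n, ")")
  # tolerant orientation per marker from across-environment class means
  orientation <- vapply(pool, function(m) {
    cm <- tapply(y, a[m, ], mean)
    names(cm)[order(cm, names(cm))][1]
  }, character(1))
  X <- t(a == orientation[pool]) * 1       # n x p indicator matrix
  colnames(X) <- pool
  tss <- sum((y - mean(y))^2)

  subsets <- lapply(seq_len(2^p - 1), function(code)
    which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0))
  rows <- vector("list", length(subsets))
  skipped <- 0L
  for (s in seq_along(subsets)) {
    idx <- subsets[[s]]
    Xs <- cbind(`(Intercept)` = 1, X[, idx, drop = FALSE])
    qrX <- qr(Xs)
    if (qrX$rank < ncol(Xs)) { skipped <- skipped + 1L; next }
    beta <- qr.coef(qrX, y)
    rss <- sum(qr.resid(qrX, y)^2)
    k <- length(idx)
    rows[[s]] <- list(idx = idx, beta = beta[-1], rss = rss,
                      aic = n * log(rss / n) + 2 * (k + 1),
                      pve = 100 * (1 - rss / tss), size = k)
  }
  if (skipped)
    message(skipped, " singular subset(s) skipped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  aics <- vapply(rows, `[[`, numeric(1), "aic")
  sizes <- vapply(rows, `[[`, numeric(1), "size")
  lab <- vapply(rows, function(r) paste(pool[r$idx], collapse = ","),
                character(1))
  ord <- order(round(aics / 1e-9) * 1e-9, sizes, lab)
  ord <- ord[seq_len(min(kTop, length(ord)))]
  eff <- matrix(NA_real_, length(ord), p, dimnames = list(NULL, pool))
  for (i in seq_along(ord))
    eff[i, rows[[ord[i]]]$idx] <- rows[[ord[i]]]$beta
  models <- data.frame(rank = seq_along(ord), markers = lab[ord],
                       size = sizes[ord], stringsAsFactors = FALSE)
  models <- cbind(models, as.data.frame(eff))
  models$pve <- vapply(rows[ord], `[[`, numeric(1), "pve")
  models$aic <- aics[ord]
  list(models = models, orientation = orientation, n = n,
       nSubsets = length(rows))
}
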