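#' Single-marker allelic-effect regression
#'
#' Regresses genotype BLUP GI values on a 0/1 allele indicator for one
#' marker. Only homozygous calls are used; the tolerant allele is the
#' allele class with the *lower* mean GI in the fit (stronger dormancy),
#' coded 1, so the slope (the allelic effect in GI units) is always
#' \eqn{\le 0} and equals the difference of class means. Reported are
#' the effect, its relative change against the susceptible-class mean,
#' the percent of phenotypic variance explained (regression
#' \eqn{R^2 \times 100}) and the two-sided p-value of the slope.
#'
#' @param blup \code{data.frame} with \code{genotype_id} and
#'   \code{blup_gi} for one environment (or the across-environment
#'   BLUPs).
#' @param panel a \linkS4class{MarkerPanel}.
#' @param marker marker identifier.
#' @param environment label stored in the result (default
#'   \code{"across"}).
#' @return one-row \code{data.frame}: \code{marker_id},
#'   \code{environment_id}, \code{tolerant_allele},
#'   \code{susceptible_allele}, \code{freq_tolerant}, \code{effect},
#'   \code{relative_change}, \code{pve}, \code{p_value},
#'   \code{n_tolerant}, \code{n_susceptible}, \code{note}. Monomorphic
#'   markers yield \code{NA} estimates with \code{note =
#'   "monomorphic"}; a class with fewer than 2 genotypes is still fit
#'   but flagged \code{"low_power"}.
#' @export
singleMarkerRegression <- function(blup, panel, marker,
                                   environment = "across") {
  calls <- markerCalls(panel)[marker, ]
  calls[.isHet(calls)] <- NA_character_
  allele <- setNames(.allele1(calls), names(calls))
  allele <- allele[!is.na(allele)]
  common <- intersect(blup$genotype_id, names(allele))
  y <- blup$blup_gi[match(common, blup$genotype_id)]
  a <- allele[common]
  res <- data.frame(marker_id = marker, environment_id = environment,
                    tolerant_allele = NA_character_,
                    susceptible_allele = NA_character_,
                    freq_tolerant = NA_real_, effect = NA_real_,
                    relative_change = NA_real_, pve = NA_real_,
                    p_value = NA_real_, n_tolerant = NA_integer_,
                    n_susceptible = NA_integer_, note = "",
                    stringsAsFactors = FALSE)
  classes <- sort(unique(a))
  if (length(classes) < 2) {
    res$note <- "monomorphic"
    return(res)
  }
  classMeans <- tapply(y, a, mean)
  # tolerant = lower-GI class; ties broken alphabetically
  tol <- names(classMeans)[order(classMeans, names(classMeans))][1]
  sus <- setdiff(classes, tol)
  x <- as.numeric(a == tol)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # zero-residual fits warn
  res$tolerant_allele <- tol
  res$susceptible_allele <- sus
  res$n_tolerant <- sum(x == 1)
  res$n_susceptible <- sum(x == 0)
  res$freq_tolerant <- mean(x)
  res$effect <- unname(coef(fit)["x"])
  res$pve <- if (var(y) == 0) 0 else 100 * sm$r.squared
  res$p_value <- if (nrow(sm$coefficients) > 1 && fit$df.residual > 0)
    sm$coefficients["x", "Pr(>|t|)"] else NA_real_
  res$relative_change <- relativeChange(res$effect,
                                        classMeans[[sus]])
  if (min(res$n_tolerant, res$n_susceptible) < 2)
    res$note <- "low_power"
  res
}

#' Allelic effect as percent of the susceptible-class mean
#'
#' @param effect allelic effect in GI units (tolerant minus susceptible
#'   class mean).
#' @param susceptibleMean mean GI of the susceptible allele class; must
#'   be positive for the percentage to be meaningful.
#' @return \eqn{100 \cdot effect / susceptibleMean}, or \code{NA} with a
#'   warning when the class mean is not positive.
#' @export
#' @examples
#' relativeChange(-0.10, 0.40) # -25
relativeChange <- function(effect, susceptibleMean) {
  if (is.na(susceptibleMean) || susceptibleMean <= 0) {
    warning("susceptible-class mean is not positive; ",
            "relative change undefined")
    return(NA_real_)
  }
  100 * effect / susceptibleMean
}

#' Scan all markers in all environments
#'
#' Runs [singleMarkerRegression()] for every marker against each
#' per-environment BLUP table and the across-environment BLUPs.
#'
#' @param blupsByEnv named list of BLUP \code{data.frame}s, one per
#'   environment, optionally including an \code{"across"} element.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param markers markers to scan (default: retained set if filtered,
#'   else all).
#' @return \code{data.frame}, one row per marker-environment fit.
#' @export
associationScan <- function(blupsByEnv, panel, markers = NULL) {
  if (is.null(markers)) {
    rd <- SummarizedExperiment::rowData(panel)
    markers <- if ("status" %in% colnames(rd))
      retainedMarkers(panel) else rownames(panel)
  }
  out <- list()
  for (env in names(blupsByEnv))
    for (m in markers)
      out[[length(out) + 1L]] <-
        singleMarkerRegression(blupsByEnv[[env]], panel, m,
                               environment = env)
  do.call(rbind, out)
}

#' Classify marker stability across environments
#'
#' A marker is stable when it shows a significant allelic effect
#' (p < \code{alpha}) in at least \code{minEnvs} individual
#' environments *and* the tolerant allele is the same in every
#' significant environment (a marker whose allele flips direction
#' between environments is not stable, whatever its p-values).
#'
#' @param assoc association table from [associationScan()]; rows with
#'   \code{environment_id == "across"} are ignored for the
#'   environment count.
#' @param alpha per-environment significance level (default 0.05, no
#'   multiple-testing correction, matching the single-marker
#'   treatment; set \code{bonferroni = TRUE} to divide \code{alpha} by
#'   the number of markers).
#' @param minEnvs minimum number of significant environments
#'   (default 2).
#' @param bonferroni apply a Bonferroni correction over markers.
#' @return \code{data.frame}: \code{marker_id},
#'   \code{n_significant_envs}, \code{direction_consistent},
#'   \code{stable}, \code{tolerant_allele} (from the significant
#'   environments, \code{NA} when inconsistent or never significant).
#' @export
classifyStability <- function(assoc, alpha = 0.05, minEnvs = 2L,
                              bonferroni = FALSE) {
  perEnv <- assoc[assoc$environment_id != "across", , drop = FALSE]
  markers <- unique(perEnv$marker_id)
  if (bonferroni) alpha <- alpha / length(markers)
  out <- lapply(markers, function(m) {
    rows <- perEnv[perEnv$marker_id == m, , drop = FALSE]
    sig <- !is.na(rows$p_value) & rows$p_value < alpha
    alleles <- unique(rows$tolerant_allele[sig])
    consistent <- length(alleles) <= 1
    data.frame(marker_id = m, n_significant_envs = sum(sig),
               direction_consistent = consistent,
               stable = sum(sig) >= minEnvs && consistent,
               tolerant_allele = if (consistent && length(alleles))
                 alleles else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
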