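#' Build multi-locus haplotype classes
#'
#' For an inbred panel a "haplotype" is the combination of homozygous
#' alleles across a chosen marker set. Genotypes heterozygous or
#' missing at any of the model's markers are excluded; the remaining
#' genotypes are partitioned by their allele combination. Classes with
#' a single member are flagged rare (they are excluded from mean
#' comparisons downstream).
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @param markers marker identifiers making up the model.
#' @return list with \code{membership} (\code{data.frame}:
#'   \code{genotype_id}, \code{haplotype}) and \code{classes}
#'   (\code{data.frame}: \code{haplotype}, \code{n}, \code{rare}),
#'   the haplotype written as alleles joined by \code{"/"} in marker
#'   order.
#' @export
buildHaplotypes <- function(panel, markers) {
  calls <- markerCalls(panel)[markers, , drop = FALSE]
  calls[.isHet(calls)] <- NA_character_
  a <- matrix(.allele1(calls), nrow = length(markers),
              dimnames = list(markers, colnames(calls)))
  complete <- colSums(is.na(a)) == 0
  a <- a[, complete, drop = FALSE]
  hap <- apply(a, 2, paste, collapse = "/")
  membership <- data.frame(genotype_id = colnames(a), haplotype = hap,
                           stringsAsFactors = FALSE, row.names = NULL)
  tab <- table(hap)
  classes <- data.frame(haplotype = names(tab), n = as.integer(tab),
                        rare = as.integer(tab) < 2L,
                        stringsAsFactors = FALSE)
  list(membership = membership, classes = classes, markers = markers)
}

#' Haplotype LSMeans with Tukey-Kramer letter grouping
#'
#' Compares haplotype-class GI means with the mixed model
#' \deqn{Y_{ijk} = \mu + hap_i + e_j + (hap \times e)_{ij} +
#'   g_{k(i)} + \epsilon_{ijk},}
#' haplotype, environment and their interaction fixed,
#' genotype-within-haplotype random, fitted to the per-environment
#' genotype BLUPs. LSMeans per class are compared pairwise with the
#' Tukey-Kramer adjustment (unequal class sizes) at level \code{alpha};
#' the degrees of freedom are taken from the genotype stratum
#' (containment: genotypes minus classes). Rare classes (n < 2) are
#' excluded from the model and reported with their raw mean and no
#' letter.
#'
#' @param blups stacked per-environment BLUPs (\code{genotype_id},
#'   \code{environment_id}, \code{blup_gi}).
#' @param haplotypes result of [buildHaplotypes()].
#' @param alpha significance level (default 0.05).
#' @return \code{data.frame}: \code{haplotype}, \code{n},
#'   \code{lsmean}, \code{letter} (\code{NA} for rare classes), ordered
#'   by increasing LSMean (rare classes last).
#' @export
haplotypeMixedModel <- function(blups, haplotypes, alpha = 0.05) {
  mem <- haplotypes$membership
  cls <- haplotypes$classes
  modeled <- cls$haplotype[!cls$rare]
  if (length(modeled) < 2)
    stop("need at least 2 non-rare haplotype classes")
  d <- merge(blups, mem, by = "genotype_id")
  rare <- d[!(d$haplotype %in% modeled), , drop = FALSE]
  d <- d[d$haplotype %in% modeled, , drop = FALSE]
  d$haplotype <- factor(d$haplotype)
  d$environment <- factor(d$environment_id)
  d$genotype <- factor(d$genotype_id)
  nGeno <- nlevels(d$genotype)
  containDf <- nGeno - nlevels(d$haplotype)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(blup_gi ~ haplotype * environment + (1 | genotype),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  emm <- suppressMessages(
    emmeans::emmeans(fit, ~haplotype, lmer.df = "asymptotic"))
  emm <- update(emm, df = containDf)    # containment df, genotype stratum
  lsm <- as.data.frame(emm)
  prs <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                               adjust = "tukey"))
  haps <- as.character(lsm$haplotype)
  pmat <- matrix(1, length(haps), length(haps),
                 dimnames = list(haps, haps))
  for (i in seq_len(nrow(prs))) {
    pairIds <- strsplit(prs$contrast[i], " - ", fixed = TRUE)[[1]]
    pairIds <- gsub("^\\(|\\)$", "", pairIds)
    pmat[pairIds[1], pairIds[2]] <- pmat[pairIds[2], pairIds[1]] <-
      prs$p.value[i]
  }
  means <- setNames(lsm$emmean, haps)
  lets <- letterDisplay(means, pmat, alpha = alpha, decreasing = FALSE)
  out <- data.frame(haplotype = haps, n = cls$n[match(haps, cls$haplotype)],
                    lsmean = unname(means), letter = unname(lets[haps]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lsmean), , drop = FALSE]
  if (nrow(rare)) {
    rareMeans <- tapply(rare$blup_gi, rare$haplotype, mean)
    out <- rbind(out, data.frame(
      haplotype = names(rareMeans),
      n = cls$n[match(names(rareMeans), cls$haplotype)],
      lsmean = unname(rareMeans), letter = NA_character_,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Selection efficiency of a haplotype versus a single marker
#'
#' Compares the genotypes selected by the best haplotype of a
#' multi-marker model with those selected by the tolerant allele class
#' of the best single marker: a two-sided Welch t-test on the members'
#' across-environment BLUP GIs, and the overlap of each selected set
#' with the top-20\% most dormant genotypes (the
#' \eqn{\lfloor 0.20 n \rfloor} genotypes of lowest across-environment
#' BLUP GI; ties broken by identifier order).
#'
#' @param blupAcross across-environment BLUP table.
#' @param haplotypeMembers genotype identifiers of the best haplotype
#'   class.
#' @param markerMembers genotype identifiers of the single-marker
#'   tolerant class.
#' @param top fraction defining the most-dormant set (default 0.20).
#' @return one-row \code{data.frame}: \code{hap_mean_gi},
#'   \code{marker_mean_gi}, \code{t_test_p} (\code{NA} when a set has
#'   fewer than 2 members or no variance), \code{n_hap},
#'   \code{n_marker}, \code{top_size}, \code{hap_in_top},
#'   \code{marker_in_top}.
#' @export
selectionEfficiency <- function(blupAcross, haplotypeMembers,
                                markerMembers, top = 0.20) {
  stopifnot(length(haplotypeMembers) > 0, length(markerMembers) > 0)
  gi <- setNames(blupAcross$blup_gi, blupAcross$genotype_id)
  ord <- order(blupAcross$blup_gi, blupAcross$genotype_id)
  topSize <- floor(top * nrow(blupAcross))
  topSet <- blupAcross$genotype_id[ord][seq_len(topSize)]
  hy <- gi[intersect(haplotypeMembers, names(gi))]
  my <- gi[intersect(markerMembers, names(gi))]
  p <- if (length(hy) < 2 || length(my) < 2 ||
           (var(hy) == 0 && var(my) == 0)) NA_real_
       else tryCatch(t.test(hy, my)$p.value, error = function(e) NA_real_)
  data.frame(hap_mean_gi = mean(hy), marker_mean_gi = mean(my),
             t_test_p = p, n_hap = length(hy), n_marker = length(my),
             top_size = topSize,
             hap_in_top = length(intersect(names(hy), topSet)),
             marker_in_top = length(intersect(names(my), topSet)))
}
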