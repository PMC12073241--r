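#' Default synthetic marker panel specification
#'
#' A 38-marker panel whose composition emulates a realistic KASP
#' validation assay: 22 usable polymorphic markers (one large-effect
#' dormancy locus at tolerant-allele frequency 0.58 with effect -0.14
#' GI, a closely linked marker, several small-effect loci, two
#' complete-LD pairs, a handful of null markers across the frequency
#' spectrum, moderate missingness up to 16\% and heterozygosity up to
#' 3\%), plus the contamination typical of such assays: 6 markers with
#' 70--96\% missing calls (failed assays), 2 markers with gross excess
#' heterozygosity (32.5\% and 65.5\%), 7 monomorphic markers and 1
#' marker at minor allele frequency 0.02. Two markers are flagged as
#' designed on the complementary strand.
#'
#' @return \code{data.frame} with one row per marker: \code{marker_id},
#'   \code{chromosome}, \code{allele1}, \code{allele2}, \code{freq1}
#'   (population frequency of the allele1 homozygote class),
#'   \code{effect1} (latent GI effect of the allele1 class relative to
#'   the allele2 class; negative = allele1 tolerant), \code{missing_rate},
#'   \code{het_rate}, \code{ld_partner} (identifier of the marker whose
#'   allele partition this marker copies, or \code{NA}),
#'   \code{strand_flag}, \code{role}.
#' @export
defaultMarkerSpec <- function() {
  mk <- function(id, chr, a1, a2, f, eff = 0, miss = 0, het = 0,
                 ld = NA_character_, strand = FALSE, role = "clean") {
    data.frame(marker_id = id, chromosome = chr, allele1 = a1,
               allele2 = a2, freq1 = f, effect1 = eff,
               missing_rate = miss, het_rate = het, ld_partner = ld,
               strand_flag = strand, role = role,
               stringsAsFactors = FALSE)
  }
  rbind(
    # effect loci (allele1 = tolerant where effect1 < 0)
    mk("qtl4A_major",  "4A", "G", "T", 0.58, -0.14),
    mk("qtl4A_linked", "4A", "T", "C", 0.39, -0.03, miss = 0.02),
    mk("qtl3A_a",      "3A", "G", "A", 0.80, -0.02),
    mk("qtl3A_b",      "3A", "A", "T", 0.80, 0, ld = "qtl3A_a",
       strand = TRUE, role = "clean_ld"),
    mk("qtl4A_ld_a",   "4A", "T", "C", 0.20, -0.03, miss = 0.01),
    mk("qtl4A_ld_b",   "4A", "A", "G", 0.20, 0, ld = "qtl4A_ld_a",
       role = "clean_ld"),
    mk("qtl3B",        "3B", "G", "A", 0.78, -0.02, het = 0.01),
    mk("qtl4A_minor",  "4A", "G", "A", 0.31, -0.02),
    mk("qtl7B",        "7B", "T", "C", 0.70, -0.01, miss = 0.05),
    # null polymorphic markers
    mk("null2A_rare",  "2A", "A", "G", 0.04),
    mk("null3B_a",     "3B", "C", "T", 0.43, het = 0.01),
    mk("null5A_a",     "5A", "A", "C", 0.25, miss = 0.095),
    mk("null5A_b",     "5A", "G", "T", 0.50, miss = 0.05),
    mk("null5B_a",     "5B", "T", "A", 0.35, het = 0.02),
    mk("null7A_a",     "7A", "C", "G", 0.15, miss = 0.08),
    mk("null7A_b",     "7A", "A", "T", 0.60, het = 0.03),
    mk("null7D_a",     "7D", "G", "C", 0.45, miss = 0.11),
    mk("null2B_a",     "2B", "T", "G", 0.28, miss = 0.12),
    mk("null3A_c",     "3A", "C", "A", 0.55, miss = 0.13),
    mk("null4B_a",     "4B", "A", "G", 0.22, miss = 0.14),
    mk("null5B_b",     "5B", "G", "A", 0.36, miss = 0.16),
    mk("null6A_a",     "6A", "T", "C", 0.12, het = 0.02),
    # failed assays: extreme missingness
    mk("fail_m1", "2B", "A", "C", 0.50, miss = 0.705, role = "high_missing"),
    mk("fail_m2", "3B", "G", "T", 0.40, miss = 0.75,  role = "high_missing"),
    mk("fail_m3", "4A", "C", "T", 0.30, miss = 0.80,  role = "high_missing"),
    mk("fail_m4", "5A", "T", "G", 0.50, miss = 0.85,  role = "high_missing"),
    mk("fail_m5", "7B", "A", "G", 0.60, miss = 0.90,  role = "high_missing"),
    mk("fail_m6", "7D", "G", "A", 0.45, miss = 0.955, role = "high_missing"),
    # gross excess heterozygosity
    mk("fail_h1", "2A", "C", "G", 0.50, het = 0.325, role = "high_het"),
    mk("fail_h2", "5B", "T", "A", 0.45, het = 0.655, role = "high_het"),
    # monomorphic
    mk("mono1", "3A", "T", "C", 1, role = "monomorphic", strand = TRUE),
    mk("mono2", "2B", "G", "A", 1, role = "monomorphic"),
    mk("mono3", "3B", "A", "T", 1, role = "monomorphic"),
    mk("mono4", "4B", "C", "G", 1, role = "monomorphic"),
    mk("mono5", "5A", "G", "T", 1, role = "monomorphic"),
    mk("mono6", "7A", "T", "A", 1, role = "monomorphic"),
    mk("mono7", "7D", "A", "C", 1, role = "monomorphic"),
    # minor allele frequency below the usable range
    mk("rare1", "6A", "G", "A", 0.02, role = "low_maf"))
}

#' Simulation configuration
#'
#' Bundles the design constants and generating parameters of a
#' synthetic multi-environment germination trial. Defaults emulate a
#' 200-genotype panel phenotyped in 4 environments with 2 replicates
#' and 40-seed germination tests, with variance components in the
#' proportions typical of such trials (genotype 0.031, environment
#' 0.015, genotype-by-environment 0.018, residual 0.003 GI^2; the
#' replicate-within-environment stratum, rarely reported, is set to a
#' nominal 0.001) and a grand-mean GI of 0.35.
#'
#' @param nGenotypes,nEnvironments,nReplicates design sizes.
#' @param seedsPerTest seeds per germination test (N).
#' @param mu grand-mean latent GI.
#' @param varG total genotypic variance (marker loci plus polygenic
#'   background; the polygenic component is \code{varG} minus the
#'   variance contributed by the specified marker effects).
#' @param varE,varGxE,varRep,varEps environment, interaction,
#'   replicate-within-environment and residual variances (latent
#'   scale; the binomial seed-count sampling adds its own noise on
#'   top of \code{varEps}).
#' @param markers marker specification table, see [defaultMarkerSpec()].
#' @param envEffects optional fixed environment effects (length
#'   \code{nEnvironments}, deviations from \code{mu}); drawn from
#'   \code{N(0, varE)} when \code{NULL}.
#' @param truncateRange bounds for the latent plot mean.
#' @param overdispersion beta-binomial overdispersion rho in [0, 1);
#'   0 (default) gives plain binomial seed counts.
#' @param rngSeed seed applied by [simulateStudy()]/[simulatePanel()].
#' @return a validated configuration list (class
#'   \code{"SimulationConfig"}).
#' @export
simulationConfig <- function(nGenotypes = 200, nEnvironments = 4,
                             nReplicates = 2, seedsPerTest = 40,
                             mu = 0.35, varG = 0.031, varE = 0.015,
                             varGxE = 0.018, varRep = 0.001,
                             varEps = 0.003,
                             markers = defaultMarkerSpec(),
                             envEffects = NULL,
                             truncateRange = c(0.02, 0.98),
                             overdispersion = 0, rngSeed = NULL) {
  cfg <- list(nGenotypes = as.integer(nGenotypes),
              nEnvironments = as.integer(nEnvironments),
              nReplicates = as.integer(nReplicates),
              seedsPerTest = as.integer(seedsPerTest), mu = mu,
              varG = varG, varE = varE, varGxE = varGxE,
              varRep = varRep, varEps = varEps, markers = markers,
              envEffects = envEffects, truncateRange = truncateRange,
              overdispersion = overdispersion, rngSeed = rngSeed)
  stopifnot(cfg$nGenotypes >= 2, cfg$nEnvironments >= 1,
            cfg$nReplicates >= 1, cfg$seedsPerTest >= 1,
            all(c(varG, varE, varGxE, varRep, varEps) >= 0),
            all(markers$freq1 >= 0 & markers$freq1 <= 1),
            all(markers$missing_rate >= 0 & markers$missing_rate <= 1),
            all(markers$het_rate >= 0 & markers$het_rate <= 1),
            overdispersion >= 0, overdispersion < 1)
  badLd <- !is.na(markers$ld_partner) &
    !(markers$ld_partner %in% markers$marker_id)
  if (any(badLd))
    stop("ld_partner references unknown marker(s): ",
         paste(markers$marker_id[badLd], collapse = ", "))
  if (!is.null(envEffects) && length(envEffects) != cfg$nEnvironments)
    stop("envEffects must have length nEnvironments")
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

#' Simulate a genotype panel with known ground truth
#'
#' Draws marker calls per the configured allele frequencies using
#' exact-count assignment (the configured number of allele1 homozygotes
#' is assigned to a random subset of genotypes), so the realized
#' frequency equals the target up to rounding and the panel's QC
#' composition is stable across seeds. Complete-LD partners copy the
#' partner's allele partition under their own labels; heterozygous and
#' missing contamination is injected at the configured exact counts at
#' random positions; strand-flagged markers are emitted as
#' complements of their nominal alleles (so that [harmonizeStrand()]
#' restores them).
#'
#' @param config a [simulationConfig()].
#' @param seed optional seed (defaults to \code{config$rngSeed}); use
#'   \code{NA} to continue the current RNG stream.
#' @return list with \code{panel} (a \linkS4class{MarkerPanel}) and
#'   \code{truth} (per-genotype latent genetic value, per-marker true
#'   effects, realized variance contributions).
#' @export
simulatePanel <- function(config = simulationConfig(),
                          seed = config$rngSeed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  mk <- config$markers
  n <- config$nGenotypes
  genos <- sprintf("cv%03d", seq_len(n))
  # allele1-class membership per marker (TRUE = allele1 homozygote)
  classOf <- matrix(FALSE, nrow(mk), n,
                    dimnames = list(mk$marker_id, genos))
  for (i in seq_len(nrow(mk))) {
    if (!is.na(mk$ld_partner[i])) next
    n1 <- round(mk$freq1[i] * n)
    classOf[i, sample.int(n, n1)] <- TRUE
  }
  for (i in which(!is.na(mk$ld_partner)))
    classOf[i, ] <- classOf[mk$ld_partner[i], ]
  # genetic values: centred marker contributions + polygenic background
  gv <- rep(0, n)
  markerVar <- 0
  for (i in seq_len(nrow(mk))) {
    if (mk$effect1[i] == 0) next
    f <- mean(classOf[i, ])
    gv <- gv + mk$effect1[i] * (classOf[i, ] - f)
    markerVar <- markerVar + f * (1 - f) * mk$effect1[i]^2
  }
  polyVar <- max(0, config$varG - markerVar)
  poly <- rnorm(n, 0, sqrt(polyVar))
  poly <- poly - mean(poly)
  gv <- gv + poly
  names(gv) <- genos
  # emit calls with contamination
  calls <- matrix(NA_character_, nrow(mk), n,
                  dimnames = list(mk$marker_id, genos))
  for (i in seq_len(nrow(mk))) {
    a1 <- mk$allele1[i]; a2 <- mk$allele2[i]
    if (mk$strand_flag[i]) {
      a1 <- .complementAllele(a1); a2 <- .complementAllele(a2)
    }
    row <- ifelse(classOf[i, ], strrep(a1, 2), strrep(a2, 2))
    nHet <- round(mk$het_rate[i] * n)
    nMiss <- round(mk$missing_rate[i] * n)
    pos <- sample.int(n, nHet + nMiss)
    if (nHet > 0)
      row[pos[seq_len(nHet)]] <- paste0(a1, a2)
    if (nMiss > 0)
      row[pos[nHet + seq_len(nMiss)]] <- NA_character_
    calls[i, ] <- row
  }
  meta <- data.frame(marker_id = mk$marker_id,
                     chromosome = mk$chromosome,
                     allele1 = ifelse(mk$strand_flag,
                                      vapply(mk$allele1, .complementAllele,
                                             character(1)),
                                      mk$allele1),
                     allele2 = ifelse(mk$strand_flag,
                                      vapply(mk$allele2, .complementAllele,
                                             character(1)),
                                      mk$allele2),
                     strand_flag = mk$strand_flag,
                     tolerant_allele = ifelse(mk$effect1 < 0, mk$allele1,
                                              ifelse(mk$effect1 > 0,
                                                     mk$allele2,
                                                     NA_character_)),
                     stringsAsFactors = FALSE)
  truth <- list(geneticValue = gv,
                markerEffects = data.frame(
                  marker_id = mk$marker_id, effect = mk$effect1,
                  tolerant_class_allele1 = mk$effect1 < 0,
                  stringsAsFactors = FALSE),
                classOf = classOf,
                polygenicVar = polyVar, markerVar = markerVar)
  list(panel = MarkerPanel(calls, meta), truth = truth)
}

# pi3 such that E[GI] = m under n3 ~ Bin(N, pi3), n6 | n3 ~ Bin(N - n3, pi3):
# E[GI] = pi3 (3 - pi3) / 2, inverted in closed form on [0, 1]
.pi3FromMean <- function(m) (3 - sqrt(9 - 8 * m)) / 2

#' Simulate multi-environment germination trials
#'
#' Generates plot-level germination counts for the panel: the latent
#' plot mean is
#' \deqn{m = \mu + G_i + e_j + (ge)_{ij} + r_{k(j)} + \epsilon_{ijk}}
#' (with \eqn{G_i} the genotype's total genetic value), truncated to
#' the configured range, and seed counts are drawn as
#' \eqn{n_3 \sim Bin(N, \pi_3)}, \eqn{n_6 \sim Bin(N - n_3, \pi_3)}
#' with \eqn{\pi_3} solved so that the expected GI equals \eqn{m}.
#' Randomness continues the current RNG stream; seed via
#' [simulateStudy()] for reproducible panel-plus-trial draws.
#'
#' @param config a [simulationConfig()].
#' @param truth ground truth from [simulatePanel()] (the per-genotype
#'   genetic values).
#' @return \code{data.frame} of plot records (\code{genotype_id},
#'   \code{environment_id}, \code{replicate}, \code{n3}, \code{n6},
#'   \code{N}) with the realized latent means and effects attached as
#'   attribute \code{"latent"}.
#' @export
simulateTrials <- function(config, truth) {
  gv <- truth$geneticValue
  genos <- names(gv)
  envs <- paste0("env", seq_len(config$nEnvironments))
  envEff <- if (!is.null(config$envEffects)) config$envEffects
            else rnorm(config$nEnvironments, 0, sqrt(config$varE))
  names(envEff) <- envs
  repEff <- matrix(rnorm(config$nEnvironments * config$nReplicates, 0,
                         sqrt(config$varRep)),
                   config$nEnvironments,
                   dimnames = list(envs,
                                   as.character(seq_len(config$nReplicates))))
  gxe <- matrix(rnorm(length(genos) * config$nEnvironments, 0,
                      sqrt(config$varGxE)),
                length(genos), dimnames = list(genos, envs))
  grid <- expand.grid(genotype_id = genos, environment_id = envs,
                      replicate = seq_len(config$nReplicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eps <- rnorm(nrow(grid), 0, sqrt(config$varEps))
  m <- config$mu + gv[grid$genotype_id] + envEff[grid$environment_id] +
    gxe[cbind(grid$genotype_id, grid$environment_id)] +
    repEff[cbind(grid$environment_id, grid$replicate)] + eps
  m <- pmin(pmax(m, config$truncateRange[1]), config$truncateRange[2])
  pi3 <- .pi3FromMean(m)
  if (config$overdispersion > 0) {
    rho <- config$overdispersion
    shape <- (1 - rho) / rho
    pi3 <- stats::rbeta(length(pi3), pi3 * shape, (1 - pi3) * shape)
  }
  N <- config$seedsPerTest
  n3 <- rbinom(nrow(grid), N, pi3)
  n6 <- rbinom(nrow(grid), N - n3, pi3)
  out <- data.frame(grid, n3 = n3, n6 = n6, N = N,
                    stringsAsFactors = FALSE)
  attr(out, "latent") <- list(m = m, envEffects = envEff,
                              repEffects = repEff, gxe = gxe)
  out
}

#' Simulate a complete study (panel + trials)
#'
#' Seeds the RNG once and draws the genotype panel and the plot-level
#' germination records in a single reproducible stream.
#'
#' @param config a [simulationConfig()].
#' @param seed optional override of \code{config$rngSeed}.
#' @return list with \code{panel}, \code{truth}, \code{plots}.
#' @export
simulateStudy <- function(config = simulationConfig(),
                          seed = config$rngSeed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  sim <- simulatePanel(config, seed = NA)
  plots <- simulateTrials(config, sim$truth)
  list(panel = sim$panel, truth = sim$truth, plots = plots)
}
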