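#' Fit the within-environment genotype model and extract BLUPs
#'
#' Fits the randomized-complete-block model for one environment,
#' \deqn{Y_{ik} = \mu + g_i + r_k + \epsilon_{ik},}
#' with genotype and replicate effects random, by REML
#' (\code{lme4::lmer}). The BLUP of genotype \eqn{i} is the shrunken
#' genotype mean \eqn{\mu + \hat g_i}. On balanced data the REML
#' solution coincides with the closed-form expected-mean-squares (ANOVA)
#' solution, which is also available directly via
#' \code{method = "anova"} and is used automatically when the data are
#' degenerate for REML (zero residual variance).
#'
#' @param gi \code{data.frame} of GI records (\code{genotype_id},
#'   \code{replicate}, \code{gi}; an \code{environment_id} column, if
#'   present, must contain a single level).
#' @param method \code{"reml"} (default) or \code{"anova"}
#'   (expected-mean-squares; balanced data only).
#' @param repRandom treat the replicate effect as random (default); if
#'   \code{FALSE} replicate enters as a fixed block effect.
#' @return list with \code{blup} (\code{data.frame}: \code{genotype_id},
#'   \code{effect}, \code{blup_gi}), \code{vc}
#'   (\linkS4class{VarianceComponents} restricted to genotype, replicate
#'   and residual), \code{mu} and, for REML fits, the underlying
#'   \code{fit}.
#' @export
fitWithinEnv <- function(gi, method = c("reml", "anova"),
                         repRandom = TRUE) {
  method <- match.arg(method)
  if ("environment_id" %in% colnames(gi) &&
      length(unique(gi$environment_id)) > 1)
    stop("fitWithinEnv() expects records from a single environment; ",
         "use fitAcrossEnv() for multi-environment data")
  d <- data.frame(genotype = factor(gi$genotype_id),
                  replicate = factor(gi$replicate), y = gi$gi)
  if (nlevels(d$genotype) < 2)
    stop("model degenerate: fewer than 2 genotypes")
  nRep <- nlevels(d$replicate)
  mu <- mean(d$y)

  if (var(d$y) == 0) {  # all observations identical: every component 0
    return(list(
      blup = data.frame(genotype_id = levels(d$genotype), effect = 0,
                        blup_gi = mu, stringsAsFactors = FALSE),
      vc = VarianceComponents(g = 0, rep = 0, eps = 0, nEnv = 1L,
                              nRep = nRep, method = method),
      mu = mu))
  }

  balanced <- all(table(d$genotype, d$replicate) == 1)
  ems <- if (balanced) suppressMessages(.emsWithin(d)) else NULL
  if (method == "anova" ||
      (balanced && !is.null(ems) && ems["eps"] < 1e-12)) {
    if (!balanced)
      stop("method = 'anova' requires balanced data; use REML")
    if (method == "reml")
      message("residual variance is zero; using the closed-form ",
              "ANOVA solution (BLUPs equal genotype means)")
    shrink <- if (ems["g"] + ems["eps"] / nRep == 0) 0 else
      ems["g"] / (ems["g"] + ems["eps"] / nRep)
    gm <- tapply(d$y, d$genotype, mean)
    eff <- unname(shrink * (gm - mu))
    return(list(
      blup = data.frame(genotype_id = names(gm), effect = eff,
                        blup_gi = mu + eff, stringsAsFactors = FALSE),
      vc = VarianceComponents(g = ems[["g"]], rep = ems[["rep"]],
                              eps = ems[["eps"]], nEnv = 1L,
                              nRep = nRep, method = "anova"),
      mu = mu))
  }

  form <- if (repRandom && nRep > 1) y ~ 1 + (1 | genotype) + (1 | replicate)
          else if (!repRandom && nRep > 1) y ~ replicate + (1 | genotype)
          else y ~ 1 + (1 | genotype)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(
                 optimizer = "nloptwrap",
                 optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12),
                 check.conv.singular = "ignore"))))
  vcdf <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vcdf$vcov[vcdf$grp == grp]
    if (length(v)) v else NA_real_
  }
  eff <- lme4::ranef(fit)$genotype
  muHat <- unname(lme4::fixef(fit)["(Intercept)"])
  list(
    blup = data.frame(genotype_id = rownames(eff),
                      effect = eff[["(Intercept)"]],
                      blup_gi = muHat + eff[["(Intercept)"]],
                      stringsAsFactors = FALSE),
    vc = VarianceComponents(g = getv("genotype"),
                            rep = if (repRandom) getv("replicate") else NA_real_,
                            eps = getv("Residual"),
                            nEnv = 1L, nRep = nRep, method = "reml"),
    mu = muHat, fit = fit)
}

#' Fit the across-environment model: BLUPs and variance components
#'
#' Fits the all-random multi-environment model
#' \deqn{Y_{ijk} = \mu + g_i + e_j + r_{k(j)} + (ge)_{ij} +
#'   \epsilon_{ijk}}
#' by REML and returns the across-environment genotype BLUPs together
#' with the five variance components. With a single environment the call
#' is delegated to [fitWithinEnv()] with a warning.
#'
#' @param gi \code{data.frame} of GI records (\code{genotype_id},
#'   \code{environment_id}, \code{replicate}, \code{gi}).
#' @return list with \code{blup}, \code{vc}
#'   (\linkS4class{VarianceComponents}), \code{mu} and \code{fit} as in
#'   [fitWithinEnv()].
#' @export
fitAcrossEnv <- function(gi) {
  envs <- unique(gi$environment_id)
  if (length(envs) < 2) {
    warning("single environment supplied; delegating to fitWithinEnv()")
    return(fitWithinEnv(gi))
  }
  d <- data.frame(genotype = factor(gi$genotype_id),
                  environment = factor(gi$environment_id),
                  replicate = factor(gi$replicate), y = gi$gi)
  if (nlevels(d$genotype) < 2)
    stop("model degenerate: fewer than 2 genotypes")
  d$repInEnv <- interaction(d$environment, d$replicate, drop = TRUE)
  nEnv <- nlevels(d$environment)
  nRep <- nlevels(d$replicate)
  mu <- mean(d$y)
  if (var(d$y) == 0) {
    return(list(
      blup = data.frame(genotype_id = levels(d$genotype), effect = 0,
                        blup_gi = mu, stringsAsFactors = FALSE),
      vc = VarianceComponents(g = 0, e = 0, gxe = 0, rep = 0, eps = 0,
                              nEnv = nEnv, nRep = nRep,
                              method = "reml"),
      mu = mu))
  }
  ctrl <- lme4::lmerControl(
    optimizer = "nloptwrap",
    optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12),
    check.conv.singular = "ignore")
  form <- y ~ 1 + (1 | genotype) + (1 | environment) +
    (1 | repInEnv) + (1 | genotype:environment)
  # on balanced data start the optimizer at the closed-form EMS
  # solution (which REML must reproduce when it is interior)
  start <- NULL
  balanced <- all(table(d$genotype, d$environment, d$replicate) == 1)
  if (balanced) {
    ems <- suppressMessages(.emsAcross(d))
    if (all(ems > 0)) {
      lf <- suppressMessages(lme4::lFormula(form, data = d, REML = TRUE))
      map <- c(genotype = "g", environment = "e", repInEnv = "rep",
               `genotype:environment` = "gxe")
      start <- list(theta = sqrt(
        ems[map[names(lf$reTrms$cnms)]] / ems[["eps"]]))
    }
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE, start = start,
               control = ctrl)))
  vcdf <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vcdf$vcov[vcdf$grp == grp]
    if (length(v)) v else 0
  }
  eff <- lme4::ranef(fit)$genotype
  muHat <- unname(lme4::fixef(fit)["(Intercept)"])
  list(
    blup = data.frame(genotype_id = rownames(eff),
                      effect = eff[["(Intercept)"]],
                      blup_gi = muHat + eff[["(Intercept)"]],
                      stringsAsFactors = FALSE),
    vc = VarianceComponents(g = getv("genotype"), e = getv("environment"),
                            gxe = getv("genotype:environment"),
                            rep = getv("repInEnv"), eps = getv("Residual"),
                            nEnv = nEnv, nRep = nRep, method = "reml"),
    mu = muHat, fit = fit)
}

# closed-form expected-mean-squares estimates, within-environment model
# (balanced data); negative estimates truncated at zero
.emsWithin <- function(d) {
  G <- nlevels(d$genotype); R <- nlevels(d$replicate)
  grand <- mean(d$y)
  gm <- tapply(d$y, d$genotype, mean)
  rm <- tapply(d$y, d$replicate, mean)
  msG <- R * sum((gm - grand)^2) / (G - 1)
  msR <- if (R > 1) G * sum((rm - grand)^2) / (R - 1) else NA_real_
  fitted <- gm[d$genotype] + (if (R > 1) rm[d$replicate] else 0) -
    (if (R > 1) grand else 0)
  ssE <- sum((d$y - fitted)^2)
  dfE <- (G - 1) * (R - 1)
  msE <- if (dfE > 0) ssE / dfE else 0
  out <- c(g = (msG - msE) / R,
           rep = if (R > 1) (msR - msE) / G else NA_real_,
           eps = msE)
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    message("EMS estimate(s) negative, truncated at 0: ",
            paste(names(out)[neg], collapse = ", "))
    out[neg] <- 0
  }
  out
}

# closed-form EMS estimates for the balanced across-environment model
.emsAcross <- function(d) {
  G <- nlevels(d$genotype); E <- nlevels(d$environment)
  R <- nlevels(d$replicate)
  grand <- mean(d$y)
  gm <- tapply(d$y, d$genotype, mean)
  em <- tapply(d$y, d$environment, mean)
  cellGE <- tapply(d$y, list(d$genotype, d$environment), mean)
  cellER <- tapply(d$y, list(d$environment, d$replicate), mean)
  msG <- E * R * sum((gm - grand)^2) / (G - 1)
  msE <- G * R * sum((em - grand)^2) / (E - 1)
  msRE <- G * sum((sweep(cellER, 1, em))^2) / (E * (R - 1))
  dev <- sweep(sweep(cellGE, 1, gm), 2, em) + grand
  msGE <- R * sum(dev^2) / ((G - 1) * (E - 1))
  fitted <- cellGE[cbind(as.integer(d$genotype), as.integer(d$environment))] +
    cellER[cbind(as.integer(d$environment), as.integer(d$replicate))] -
    em[as.integer(d$environment)]
  msErr <- sum((d$y - fitted)^2) / (E * (G - 1) * (R - 1))
  out <- c(g = (msG - msGE) / (E * R),
           e = (msE - msGE - msRE + msErr) / (G * R),
           gxe = (msGE - msErr) / R,
           rep = (msRE - msErr) / G,
           eps = msErr)
  neg <- out < 0
  if (any(neg)) {
    message("EMS estimate(s) negative, truncated at 0: ",
            paste(names(out)[neg], collapse = ", "))
    out[neg] <- 0
  }
  out
}

#' Expected-mean-squares (ANOVA) variance components on balanced data
#'
#' Closed-form method-of-moments estimates used as the balanced-data
#' cross-check for the REML fits (the two must agree on balanced data)
#' and as starting values. Negative solutions are truncated at zero
#' with a message.
#'
#' @param gi GI records as for [fitAcrossEnv()] (or, with a single
#'   environment, [fitWithinEnv()]); must form a complete balanced
#'   layout.
#' @return \linkS4class{VarianceComponents}.
#' @export
emsComponents <- function(gi) {
  d <- data.frame(genotype = factor(gi$genotype_id),
                  environment = if ("environment_id" %in% colnames(gi))
                    factor(gi$environment_id) else factor("env"),
                  replicate = factor(gi$replicate), y = gi$gi)
  if (any(table(d$genotype, d$environment, d$replicate) != 1))
    stop("emsComponents() requires one observation per ",
         "genotype x environment x replicate cell")
  if (nlevels(d$environment) == 1) {
    s <- .emsWithin(d)
    VarianceComponents(g = s[["g"]], rep = s[["rep"]], eps = s[["eps"]],
                       nEnv = 1L, nRep = nlevels(d$replicate),
                       method = "anova")
  } else {
    s <- .emsAcross(d)
    VarianceComponents(g = s[["g"]], e = s[["e"]], gxe = s[["gxe"]],
                       rep = s[["rep"]], eps = s[["eps"]],
                       nEnv = nlevels(d$environment),
                       nRep = nlevels(d$replicate), method = "anova")
  }
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{g\times e}/e +
#'   \sigma^2_\epsilon/(e r)}}
#' with \eqn{e} environments and \eqn{r} replicates. For a
#' within-environment fit (\eqn{e = 1}) the interaction term is absent.
#'
#' @param object a \linkS4class{VarianceComponents}.
#' @param ... unused.
#' @return heritability in \eqn{[0, 1]}.
#' @export
#' @examples
#' heritability(VarianceComponents(g = 0.031, gxe = 0.018, eps = 0.003,
#'                                 nEnv = 4, nRep = 2)) # 0.864
setGeneric("heritability", function(object, ...)
  standardGeneric("heritability"))

#' @rdname heritability
#' @export
setMethod("heritability", "VarianceComponents", function(object, ...) {
  s <- object@sigma2
  gxe <- if (is.na(s["gxe"])) {
    if (object@nEnv > 1L)
      stop("genotype-by-environment component missing from a ",
           "multi-environment fit")
    0
  } else s[["gxe"]]
  g <- s[["g"]]; eps <- s[["eps"]]
  if (is.na(g) || is.na(eps)) stop("incomplete variance components")
  denom <- g + gxe / object@nEnv + eps / (object@nEnv * object@nRep)
  if (denom == 0)
    stop("heritability undefined: genotype, interaction and residual ",
         "variances are all zero")
  g / denom
})

#' Percentage shares of the total phenotypic variance
#'
#' Shares of the four-term total \eqn{\sigma^2_g + \sigma^2_e +
#' \sigma^2_{g\times e} + \sigma^2_\epsilon} (the replicate stratum is
#' not part of the reported decomposition), rounded to integer percent.
#'
#' @param vc a \linkS4class{VarianceComponents} from an
#'   across-environment fit.
#' @return named numeric (\code{g}, \code{e}, \code{gxe}, \code{eps}),
#'   integer percentages.
#' @export
#' @examples
#' vc <- VarianceComponents(g = 0.031, e = 0.015, gxe = 0.018,
#'                          eps = 0.003, nEnv = 4, nRep = 2)
#' varianceShares(vc) # 46, 22, 27, 4
varianceShares <- function(vc) {
  s <- vc@sigma2[c("g", "e", "gxe", "eps")]
  if (anyNA(s))
    stop("variance shares need the across-environment components ",
         "(g, e, gxe, eps)")
  total <- sum(s)
  if (total <= 0) stop("total phenotypic variance is zero")
  out <- roundHalfUp(100 * s / total)
  names(out) <- c("g", "e", "gxe", "eps")
  out
}

#' Compare environment means by Tukey's HSD
#'
#' Fits the two-way fixed-effects model \eqn{Y_{ij} = \mu + g_i + e_j +
#' \epsilon_{ij}} to the per-environment genotype BLUPs and compares
#' environment means with Tukey's Studentized Range test
#' (Tukey-Kramer under mild imbalance), emitting a compact letter
#' display. Environments are reported from highest to lowest mean GI,
#' letters assigned in that order.
#'
#' @param blups \code{data.frame} of stacked per-environment BLUPs
#'   (\code{genotype_id}, \code{environment_id}, \code{blup_gi}).
#' @param alpha significance level (default 0.05).
#' @return \code{data.frame}: \code{environment_id}, \code{mean},
#'   \code{sd}, \code{min}, \code{max}, \code{letter}, ordered by
#'   decreasing mean.
#' @export
compareEnvMeans <- function(blups, alpha = 0.05) {
  d <- data.frame(genotype = factor(blups$genotype_id),
                  environment = factor(blups$environment_id),
                  y = blups$blup_gi)
  if (nlevels(d$environment) < 2)
    stop("need at least 2 environments to compare")
  counts <- table(d$genotype, d$environment)
  if (any(counts == 0))
    message("unbalanced genotype coverage across environments; ",
            "proceeding with available cells (Tukey-Kramer)")
  fit <- aov(y ~ genotype + environment, data = d)
  tk <- TukeyHSD(fit, "environment")$environment
  envs <- levels(d$environment)
  pmat <- matrix(1, length(envs), length(envs),
                 dimnames = list(envs, envs))
  pairNames <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairNames)) {
    a <- pairNames[[i]][1]; b <- pairNames[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  means <- tapply(d$y, d$environment, mean)
  letters <- letterDisplay(means, pmat, alpha = alpha,
                           decreasing = TRUE)
  ord <- order(means, decreasing = TRUE)
  data.frame(environment_id = envs[ord],
             mean = unname(means[ord]),
             sd = unname(tapply(d$y, d$environment, sd)[ord]),
             min = unname(tapply(d$y, d$environment, min)[ord]),
             max = unname(tapply(d$y, d$environment, max)[ord]),
             letter = unname(letters[ord]),
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise adjusted p-values
#'
#' Groups are connected when their pairwise adjusted p-value exceeds
#' \code{alpha}; letters correspond to the maximal cliques of that
#' graph, ordered along the means, so that (i) any two groups sharing a
#' letter are not significantly different and (ii) any non-significant
#' pair shares at least one letter.
#'
#' @param means named numeric of group means.
#' @param pmat symmetric matrix of pairwise adjusted p-values with
#'   dimnames matching \code{names(means)}.
#' @param alpha significance level.
#' @param decreasing assign letters walking from the highest mean
#'   (\code{TRUE}, environment-table convention) or the lowest
#'   (\code{FALSE}, haplotype-table convention).
#' @return named character vector of letter strings.
#' @export
letterDisplay <- function(means, pmat, alpha = 0.05,
                          decreasing = FALSE) {
  groups <- names(means)
  stopifnot(!is.null(groups), all(groups %in% rownames(pmat)))
  k <- length(groups)
  adj <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) for (j in seq_len(k))
    adj[i, j] <- i == j || pmat[groups[i], groups[j]] > alpha
  cliques <- .maximalCliques(adj)
  ord <- order(means, decreasing = decreasing)
  pos <- match(seq_len(k), ord)  # rank of each group along the walk
  cliques <- cliques[order(vapply(cliques, function(cl) min(pos[cl]),
                                  numeric(1)))]
  out <- setNames(rep("", k), groups)
  for (i in seq_along(cliques))
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  out
}

# maximal cliques of a small undirected graph (Bron-Kerbosch)
.maximalCliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    for (v in P) {
      nv <- which(adj[v, ] & seq_len(n) != v)
      bk(c(R, v), intersect(P, nv), intersect(X, nv))
      P <- setdiff(P, v)
      X <- union(X, v)
    }
  }
  bk(integer(), seq_len(n), integer())
  cliques
}
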