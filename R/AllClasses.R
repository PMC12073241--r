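#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aov anova coef lm median p.adjust pf pt ptukey qtukey
#'   rbinom rnorm runif sd setNames t.test var vcov TukeyHSD as.formula
#'   complete.cases update
#' @importFrom utils read.table write.csv head combn
NULL

#' MarkerPanel: genotype-by-marker KASP calls with per-marker metadata
#'
#' An S4 container for a biallelic marker panel, extending
#' \linkS4class{SummarizedExperiment}. The single assay, \code{"calls"},
#' is a character matrix with markers as rows and genotypes (cultivars)
#' as columns; each cell is a two-letter diploid call such as
#' \code{"GG"} (homozygous), \code{"GT"} (heterozygous) or \code{NA}
#' (no call). Per-marker annotation lives in \code{rowData}:
#' \describe{
#'   \item{chromosome}{chromosome arm the marker maps to.}
#'   \item{allele1, allele2}{the two assay alleles.}
#'   \item{strand_flag}{\code{TRUE} when the assay was designed on the
#'     strand complementary to the one the polymorphism was originally
#'     reported on; see [harmonizeStrand()].}
#'   \item{tolerant_allele}{optional prior annotation of the
#'     dormancy-increasing (low-GI) allele.}
#' }
#' QC functions ([qcStats()], [applyFilters()]) append further
#' \code{rowData} columns rather than inventing a parallel report object.
#'
#' @seealso [MarkerPanel()] for construction from a call matrix.
#' @export
setClass("MarkerPanel", contains = "SummarizedExperiment")

setValidity("MarkerPanel", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    calls <- SummarizedExperiment::assay(object, "calls")
    if (!is.character(calls))
      msg <- c(msg, "assay 'calls' must be a character matrix")
    else {
      bad <- !is.na(calls) & nchar(calls) != 2L
      if (any(bad))
        msg <- c(msg, "calls must be two-character diploid strings or NA")
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "marker identifiers must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "genotype identifiers must be unique")
  rd <- SummarizedExperiment::rowData(object)
  if (all(c("allele1", "allele2") %in% colnames(rd)) &&
      any(!is.na(rd$allele1) & !is.na(rd$allele2) &
          rd$allele1 == rd$allele2))
    msg <- c(msg, "allele1 and allele2 must differ for every marker")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerPanel
#'
#' @param calls character matrix of diploid calls, markers in rows and
#'   genotypes in columns (e.g. \code{"GG"}, \code{"GT"}, \code{NA}).
#'   Row and column names are the marker and genotype identifiers.
#' @param meta optional \code{data.frame} of marker metadata with a
#'   \code{marker_id} column matching \code{rownames(calls)} and any of
#'   \code{chromosome}, \code{allele1}, \code{allele2},
#'   \code{strand_flag}, \code{tolerant_allele}. Alleles missing from
#'   \code{meta} are inferred from the observed calls.
#' @return a \linkS4class{MarkerPanel}.
#' @export
#' @examples
#' calls <- rbind(m1 = c(g1 = "GG", g2 = "TT", g3 = "GT"),
#'                m2 = c(g1 = "AA", g2 = "AA", g3 = NA))
#' MarkerPanel(calls)
MarkerPanel <- function(calls, meta = NULL) {
  if (is.null(rownames(calls)))
    stop("'calls' must have marker identifiers as rownames")
  if (is.null(colnames(calls)))
    stop("'calls' must have genotype identifiers as colnames")
  n <- nrow(calls)
  rd <- S4Vectors::DataFrame(
    chromosome = rep(NA_character_, n),
    allele1 = NA_character_, allele2 = NA_character_,
    strand_flag = rep(FALSE, n),
    tolerant_allele = rep(NA_character_, n),
    row.names = rownames(calls))
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"marker_id" %in% colnames(meta))
      stop("'meta' needs a marker_id column")
    idx <- match(rownames(calls), meta$marker_id)
    if (anyNA(idx))
      stop("metadata missing for marker(s): ",
           paste(rownames(calls)[is.na(idx)], collapse = ", "))
    for (col in intersect(colnames(meta), colnames(rd)))
      rd[[col]] <- meta[[col]][idx]
    rd$strand_flag[is.na(rd$strand_flag)] <- FALSE
  }
  # fill alleles not given in meta from the observed calls
  for (i in seq_len(n)) {
    if (is.na(rd$allele1[i]) || is.na(rd$allele2[i])) {
      obs <- sort(unique(c(.allele1(calls[i, ]), .allele2(calls[i, ]))))
      obs <- obs[!is.na(obs)]
      rd$allele1[i] <- if (length(obs) >= 1) obs[1] else NA_character_
      rd$allele2[i] <- if (length(obs) >= 2) obs[2] else NA_character_
    }
  }
  methods::new("MarkerPanel",
               SummarizedExperiment::SummarizedExperiment(
                 assays = list(calls = calls), rowData = rd))
}

#' @describeIn MarkerPanel the call matrix (markers x genotypes).
#' @param x,object a \code{MarkerPanel}.
#' @export
markerCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @describeIn MarkerPanel marker metadata (plus any QC columns) as a
#'   \code{data.frame}.
#' @export
markerInfo <- function(x) {
  df <- as.data.frame(SummarizedExperiment::rowData(x))
  cbind(marker_id = rownames(df), df, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' @export
setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel:", nrow(object), "markers x", ncol(object),
      "genotypes\n")
  calls <- markerCalls(object)
  cat(sprintf("  calls: %.1f%% missing, %.1f%% heterozygous\n",
              100 * mean(is.na(calls)),
              100 * mean(.isHet(calls))))
  rd <- SummarizedExperiment::rowData(object)
  if ("status" %in% colnames(rd))
    cat("  QC: ", sum(rd$status == "retained"), " retained / ",
        nrow(object), " markers\n", sep = "")
})

#' VarianceComponents: variance decomposition of a germination-index trial
#'
#' Holds the REML (or ANOVA) estimates of the random-effect variances of
#' the multi-environment model
#' \deqn{Y_{ijk} = \mu + g_i + e_j + r_{k(j)} + (ge)_{ij} +
#'   \epsilon_{ijk},}
#' i.e. genotype, environment, replicate-within-environment,
#' genotype-by-environment and residual variance, together with the
#' design constants (number of environments \code{e} and replicates
#' \code{r}) needed for entry-mean heritability. Within-environment fits
#' carry \code{NA} for the environment and interaction components.
#'
#' @slot sigma2 named numeric: \code{g}, \code{e}, \code{gxe},
#'   \code{rep}, \code{eps} (GI^2 units).
#' @slot nEnv,nRep design constants.
#' @slot method estimation method ("reml" or "anova").
#' @export
setClass("VarianceComponents",
         representation(sigma2 = "numeric", nEnv = "integer",
                        nRep = "integer", method = "character"))

setValidity("VarianceComponents", function(object) {
  s <- object@sigma2
  if (!identical(names(s), c("g", "e", "gxe", "rep", "eps")))
    return("sigma2 must be named g, e, gxe, rep, eps")
  if (any(s < 0, na.rm = TRUE)) return("variance components must be >= 0")
  if (object@nEnv < 1L || object@nRep < 1L)
    return("nEnv and nRep must be >= 1")
  TRUE
})

#' Construct a VarianceComponents object
#'
#' @param g,e,gxe,rep,eps variance components (GI^2 units); components
#'   not present in a model may be \code{NA}.
#' @param nEnv,nRep number of environments and replicates.
#' @param method label of the estimation method.
#' @return a \linkS4class{VarianceComponents}.
#' @export
#' @examples
#' vc <- VarianceComponents(g = 0.031, gxe = 0.018, eps = 0.003,
#'                          nEnv = 4, nRep = 2)
#' heritability(vc)
VarianceComponents <- function(g, e = NA_real_, gxe = NA_real_,
                               rep = NA_real_, eps, nEnv, nRep,
                               method = "manual") {
  methods::new("VarianceComponents",
               sigma2 = c(g = g, e = e, gxe = gxe, rep = rep, eps = eps),
               nEnv = as.integer(nEnv), nRep = as.integer(nRep),
               method = method)
}

#' @describeIn VarianceComponents the named vector of variance
#'   components.
#' @param x,object a \code{VarianceComponents}.
#' @export
varComp <- function(x) x@sigma2

#' @export
setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", object@method, "), e = ", object@nEnv,
      ", r = ", object@nRep, "\n", sep = "")
  print(signif(object@sigma2, 4))
  h2 <- tryCatch(heritability(object), error = function(e) NA_real_)
  if (!is.na(h2)) cat("broad-sense heritability:", round(h2, 3), "\n")
})
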