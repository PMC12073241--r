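#' Per-marker QC statistics
#'
#' Computes, for every marker of the panel, the missing-call rate (over
#' all genotypes), the heterozygosity rate (over non-missing calls) and
#' the minor allele frequency (over homozygous calls only, consistent
#' with a downstream analysis restricted to homozygous genotypes).
#' Results are appended to the panel's \code{rowData} as columns
#' \code{missing_rate}, \code{het_rate}, \code{maf} and
#' \code{n_hom}. A marker with no homozygous calls gets \code{maf = NA}.
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @return the panel with QC columns filled in; retrieve them with
#'   [markerInfo()].
#' @export
qcStats <- function(panel) {
  calls <- markerCalls(panel)
  if (!length(calls)) stop("empty call matrix")
  nGeno <- ncol(calls)
  missingRate <- rowMeans(is.na(calls))
  nonMissing <- nGeno - rowSums(is.na(calls))
  hetCount <- rowSums(.isHet(calls))
  hetRate <- ifelse(nonMissing > 0, hetCount / nonMissing, NA_real_)
  maf <- numeric(nrow(calls))
  nHom <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    hom <- calls[i, .isHom(calls[i, ])]
    nHom[i] <- length(hom)
    if (!length(hom)) { maf[i] <- NA_real_; next }
    counts <- table(.allele1(hom))
    maf[i] <- if (length(counts) < 2) 0 else min(counts) / sum(counts)
  }
  rd <- SummarizedExperiment::rowData(panel)
  rd$missing_rate <- missingRate
  rd$het_rate <- hetRate
  rd$maf <- maf
  rd$n_hom <- nHom
  SummarizedExperiment::rowData(panel) <- rd
  panel
}

#' Apply the marker filter cascade
#'
#' Markers are screened in a fixed cascade: missing rate, then
#' heterozygosity, then monomorphy, then minor allele frequency; an
#' excluded marker is labelled with the *first* failing reason. The
#' default thresholds (missing rate > 0.20, heterozygosity > 0.05,
#' MAF < 0.03) separate assay failures and contaminated assays from
#' usable polymorphic markers while keeping markers with moderate
#' (10--16\%) missing data. Markers whose MAF is undefined (no
#' homozygous calls) are treated as monomorphic. The cascade is
#' idempotent: re-filtering the retained set excludes nothing further.
#'
#' @param panel a \linkS4class{MarkerPanel}; [qcStats()] is run first if
#'   its columns are absent.
#' @param maxMissing,maxHet,minMaf cascade thresholds.
#' @return the panel with \code{status} ("retained"/"excluded") and
#'   \code{reason} ("high_missing", "high_het", "monomorphic",
#'   "low_maf" or "none") columns in its \code{rowData}.
#' @export
applyFilters <- function(panel, maxMissing = 0.20, maxHet = 0.05,
                         minMaf = 0.03) {
  if (!"maf" %in% colnames(SummarizedExperiment::rowData(panel)))
    panel <- qcStats(panel)
  rd <- SummarizedExperiment::rowData(panel)
  reason <- rep("none", nrow(panel))
  reason[reason == "none" & rd$missing_rate > maxMissing] <- "high_missing"
  reason[reason == "none" & !is.na(rd$het_rate) &
           rd$het_rate > maxHet] <- "high_het"
  reason[reason == "none" & (is.na(rd$maf) | rd$maf == 0)] <- "monomorphic"
  reason[reason == "none" & rd$maf < minMaf] <- "low_maf"
  rd$status <- ifelse(reason == "none", "retained", "excluded")
  rd$reason <- reason
  SummarizedExperiment::rowData(panel) <- rd
  panel
}

#' @describeIn applyFilters identifiers of the retained markers.
#' @export
retainedMarkers <- function(panel) {
  rd <- SummarizedExperiment::rowData(panel)
  if (!"status" %in% colnames(rd))
    stop("run applyFilters() first")
  rownames(panel)[rd$status == "retained"]
}

#' Set heterozygous calls to missing
#'
#' The allelic-effect analysis considers homozygous genotypes only (the
#' panel is inbred; heterozygous calls are treated as assay artefacts).
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @return the panel with every heterozygous cell set to \code{NA}.
#' @export
dropHeterozygotes <- function(panel) {
  calls <- markerCalls(panel)
  calls[.isHet(calls)] <- NA_character_
  SummarizedExperiment::assay(panel, "calls") <- calls
  panel
}

#' Harmonize strand-complemented assays
#'
#' KASP assays designed on the strand complementary to the one a
#' polymorphism was originally reported on yield calls on the wrong
#' strand. For every marker whose \code{strand_flag} is set, calls and
#' allele labels are mapped through the nucleotide complement
#' (A<->T, C<->G) so that they match the originally reported alleles.
#' The mapping is an involution (applying it twice restores the input);
#' the flag itself marks the assay design and is not altered.
#' Indel-coded alleles cannot be complemented: a flagged non-nucleotide
#' marker is an error.
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @return the panel with flagged markers recoded.
#' @export
harmonizeStrand <- function(panel) {
  rd <- SummarizedExperiment::rowData(panel)
  flagged <- which(rd$strand_flag %in% TRUE)
  if (!length(flagged)) return(panel)
  calls <- markerCalls(panel)
  for (i in flagged) {
    calls[i, ] <- .complementCalls(calls[i, ])
    if (!is.na(rd$allele1[i]))
      rd$allele1[i] <- .complementAllele(rd$allele1[i])
    if (!is.na(rd$allele2[i]))
      rd$allele2[i] <- .complementAllele(rd$allele2[i])
    if (!is.na(rd$tolerant_allele[i]))
      rd$tolerant_allele[i] <- .complementAllele(rd$tolerant_allele[i])
  }
  SummarizedExperiment::assay(panel, "calls") <- calls
  SummarizedExperiment::rowData(panel) <- rd
  panel
}

#' Detect complete-LD marker groups
#'
#' Two markers are in complete linkage disequilibrium when, over the
#' genotypes with homozygous non-missing calls at both, their allele
#' classes partition the genotypes identically (squared allelic
#' correlation 1). Only two haplotypes are then observed for the pair,
#' and one member suffices in multi-marker models. Pairs are merged
#' into groups (equivalence classes via union-find); a representative
#' per group is nominated (fewest missing calls, ties broken by marker
#' order).
#'
#' @param panel a \linkS4class{MarkerPanel}; heterozygous calls are
#'   ignored.
#' @param markers marker identifiers to consider (default: the retained
#'   set if filters have been applied, else all markers).
#' @param minShared minimum number of jointly typed genotypes needed to
#'   declare a pair (default 2).
#' @return list of groups; each group is a list with \code{markers}
#'   (character vector) and \code{representative}. Markers in no group
#'   are their own representative and are omitted.
#' @export
detectCompleteLD <- function(panel, markers = NULL, minShared = 2L) {
  rd <- SummarizedExperiment::rowData(panel)
  if (is.null(markers))
    markers <- if ("status" %in% colnames(rd))
      retainedMarkers(panel) else rownames(panel)
  calls <- markerCalls(panel)[markers, , drop = FALSE]
  calls[.isHet(calls)] <- NA_character_
  a <- matrix(.allele1(calls), nrow = nrow(calls),
              dimnames = dimnames(calls))
  p <- length(markers)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
    shared <- !is.na(a[i, ]) & !is.na(a[j, ])
    if (sum(shared) < minShared) next
    ai <- a[i, shared]; aj <- a[j, shared]
    # identical partition: the class map must be a bijection and both
    # markers polymorphic over the shared genotypes
    if (length(unique(ai)) < 2 || length(unique(aj)) < 2) next
    tab <- table(ai, aj)
    if (all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(p), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- markers[roots == r]
    if (length(members) < 2) next
    nMissing <- rowSums(is.na(calls[members, , drop = FALSE]))
    rep_ <- members[order(nMissing, match(members, markers))][1]
    out[[length(out) + 1L]] <- list(markers = members,
                                    representative = rep_)
  }
  out
}

#' Read a KASP call matrix and marker metadata from CSV
#'
#' The call matrix has genotypes as rows and markers as columns, cells
#' as two-letter diploid calls (\code{"GG"}, \code{"GT"}, ...) or
#' \code{NA}; it is transposed into the markers-by-genotypes
#' orientation of [MarkerPanel()].
#'
#' @param callsPath path to the call matrix CSV (first column genotype
#'   identifiers).
#' @param metaPath optional path to the marker metadata CSV (see
#'   [MarkerPanel()]).
#' @return a \linkS4class{MarkerPanel}.
#' @export
readMarkerPanel <- function(callsPath, metaPath = NULL) {
  raw <- .readDelim(callsPath)
  genos <- as.character(raw[[1]])
  m <- t(as.matrix(raw[, -1, drop = FALSE]))
  mode(m) <- "character"
  m[m %in% c("NA", "")] <- NA_character_
  colnames(m) <- genos
  meta <- if (!is.null(metaPath)) .readDelim(metaPath) else NULL
  MarkerPanel(m, meta)
}
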