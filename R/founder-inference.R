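#' Assign per-marker founder labels from SNP genotypes
#'
#' At markers whose founder alleles differ, a homozygous B call becomes
#' label \code{"B"}, a homozygous D call \code{"D"}; heterozygous calls,
#' calls matching neither founder, missing calls and founder-uninformative
#' markers all carry a missing label.
#'
#' @param snp \code{SummarizedExperiment} of SNP calls (assay \code{"geno"},
#'   values \code{"B"}, \code{"H"}, \code{"D"} or \code{NA}), rows matching
#'   the panel markers.
#' @param founders a \code{\linkS4class{FounderPanel}}.
#' @return a \code{\linkS4class{FounderLabelSet}} (assay \code{"label"}).
#' @export
assignFounderLabels <- function(snp, founders) {
  mk <- founders@markers
  geno <- SummarizedExperiment::assay(snp, "geno")
  if (!identical(rownames(geno), names(mk))) {
    if (!all(rownames(geno) %in% names(mk)))
      stop("SNP table contains markers absent from the founder panel: ",
           paste(utils::head(setdiff(rownames(geno), names(mk)), 3), collapse = ", "))
    mk <- mk[rownames(geno)]
  }
  lab <- geno
  lab[!(lab %in% c("B", "D"))] <- NA_character_
  lab[mk$alleleB == mk$alleleD, ] <- NA_character_
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(label = lab), rowRanges = mk,
    colData = SummarizedExperiment::colData(snp))
  methods::new("FounderLabelSet", se)
}

# haldane recombination fraction from a cM distance, expanded for an
# RI-by-sibling panel: R = 4r / (1 + 6r)
.riTransProb <- function(dCm) {
  r <- 0.5 * (1 - exp(-2 * dCm / 100))
  pmin(0.5, 4 * r / (1 + 6 * r))
}

# forward-backward posteriors of the 2-state (B/D) founder HMM for one
# chromosome, vectorised across strains.  lab: markers x strains in
# {"B","D",NA}; returns P(state = B), same shape.
.hmmPosterior <- function(lab, cM, errorRate) {
  nM <- nrow(lab); nS <- ncol(lab)
  if (nM == 0L) return(lab)
  eB <- matrix(1, nS, nM); eD <- matrix(1, nS, nM)
  obsB <- t(lab == "B"); obsD <- t(lab == "D")   # strains x markers
  obsB[is.na(obsB)] <- FALSE; obsD[is.na(obsD)] <- FALSE
  eB[obsB] <- 1 - errorRate; eB[obsD] <- errorRate
  eD[obsD] <- 1 - errorRate; eD[obsB] <- errorRate
  R <- .riTransProb(diff(cM))
  aB <- matrix(0, nS, nM); aD <- matrix(0, nS, nM)
  aB[, 1] <- 0.5 * eB[, 1]; aD[, 1] <- 0.5 * eD[, 1]
  z <- aB[, 1] + aD[, 1]; z[z == 0] <- 1
  aB[, 1] <- aB[, 1] / z; aD[, 1] <- aD[, 1] / z
  for (m in seq_len(nM - 1L)) {
    pB <- aB[, m] * (1 - R[m]) + aD[, m] * R[m]
    pD <- aB[, m] * R[m] + aD[, m] * (1 - R[m])
    aB[, m + 1L] <- pB * eB[, m + 1L]
    aD[, m + 1L] <- pD * eD[, m + 1L]
    z <- aB[, m + 1L] + aD[, m + 1L]; z[z == 0] <- 1
    aB[, m + 1L] <- aB[, m + 1L] / z; aD[, m + 1L] <- aD[, m + 1L] / z
  }
  bB <- rep(1, nS); bD <- rep(1, nS)
  post <- matrix(0, nS, nM)
  post[, nM] <- aB[, nM] / (aB[, nM] + aD[, nM])
  for (m in rev(seq_len(nM - 1L))) {
    xB <- eB[, m + 1L] * bB; xD <- eD[, m + 1L] * bD
    bB <- xB * (1 - R[m]) + xD * R[m]
    bD <- xB * R[m] + xD * (1 - R[m])
    z <- bB + bD; z[z == 0] <- 1
    bB <- bB / z; bD <- bD / z
    num <- aB[, m] * bB
    post[, m] <- num / (num + aD[, m] * bD)
  }
  t(post)   # markers x strains
}

#' Impute missing founder labels with a two-state HMM
#'
#' Runs a two-state (B/D) hidden Markov model along each chromosome
#' (transition probability between adjacent markers: Haldane recombination
#' fraction from the cM distance, expanded for RI-by-sibling panels as
#' \code{4r/(1+6r)}; emission: the observed label matches the state with
#' probability \code{1 - errorRate}) and computes marginal posteriors by
#' forward-backward.  A missing label is replaced by the state whose
#' marginal posterior exceeds \code{minProb}; exact ties (posterior 0.5)
#' stay missing.  Observed labels are left untouched.
#'
#' @param fls a \code{\linkS4class{FounderLabelSet}}.
#' @param errorRate emission error probability (default 0.002; logged in
#'   pipeline manifests since it is a free parameter of the model).
#' @param minProb minimum marginal posterior for imputation (default 0.5).
#' @return the \code{FounderLabelSet} with imputed \code{"label"} and a new
#'   \code{"probB"} posterior assay.
#' @export
imputeFounderLabels <- function(fls, errorRate = 0.002, minProb = 0.5) {
  lab <- SummarizedExperiment::assay(fls, "label")
  rr <- SummarizedExperiment::rowRanges(fls)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pB <- matrix(NA_real_, nrow(lab), ncol(lab), dimnames = dimnames(lab))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pB[i, ] <- .hmmPosterior(lab[i, , drop = FALSE], rr$cM[i], errorRate)
  }
  out <- lab
  fill <- is.na(lab) & pB > minProb
  out[fill] <- "B"
  fill <- is.na(lab) & (1 - pB) > minProb
  out[fill] <- "D"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(label = out, probB = pB, observed = lab),
    rowRanges = rr, colData = SummarizedExperiment::colData(fls))
  methods::new("FounderLabelSet", se)
}

#' Build founder haplotype blocks from a label track
#'
#' Maximal runs of consecutive identical non-missing labels form one block
#' per strain (the connected components of the identical-adjacent-label
#' graph); unresolved missing markers between runs remain gaps, splitting
#' same-label neighbours into distinct blocks.  Block boundaries are the
#' first and last marker positions of the run.
#'
#' @param fls a \code{\linkS4class{FounderLabelSet}} (normally after
#'   \code{\link{imputeFounderLabels}}).
#' @return \code{GRanges} with metadata columns \code{strain} and
#'   \code{label}, sorted within strain.
#' @export
buildHaplotypeBlocks <- function(fls) {
  lab <- SummarizedExperiment::assay(fls, "label")
  rr <- SummarizedExperiment::rowRanges(fls)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  res <- list(); n <- 0L
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    for (s in colnames(lab)) {
      v <- lab[i, s]
      v[is.na(v)] <- "."
      r <- rle(v)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- r$values != "."
      if (!any(keep)) next
      n <- n + 1L
      res[[n]] <- data.frame(chrom = ch,
                             start = pos[i][starts[keep]],
                             end = pos[i][ends[keep]],
                             strain = s, label = r$values[keep])
    }
  }
  if (!n) return(GenomicRanges::GRanges())
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strain = df$strain, label = df$label)
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(rr)
  gr
}

# label of the block containing each position for one strain, with gap
# positions attached to the nearest block edge (bp distance); exact
# midpoint ties and positions outside any chromosome with blocks -> NA
.blockLabelsAt <- function(blocks, strain, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  bs <- blocks[blocks$strain == strain]
  bchr <- as.character(GenomeInfoDb::seqnames(bs))
  for (ch in unique(chrom)) {
    q <- which(chrom == ch)
    b <- which(bchr == ch)
    if (!length(b)) next
    st <- GenomicRanges::start(bs)[b]; en <- GenomicRanges::end(bs)[b]
    lb <- bs$label[b]
    o <- order(st); st <- st[o]; en <- en[o]; lb <- lb[o]
    p <- pos[q]
    i <- findInterval(p, st)
    lab <- rep(NA_character_, length(p))
    inside <- i >= 1L & p <= en[pmax(i, 1L)]
    lab[inside] <- lb[i[inside]]
    gap <- !inside
    if (any(gap)) {
      ig <- i[gap]; pg <- p[gap]
      dl <- ifelse(ig >= 1L, pg - en[pmax(ig, 1L)], Inf)
      dr <- ifelse(ig < length(st), st[pmin(ig + 1L, length(st))] - pg, Inf)
      lab[gap][dl < dr] <- lb[pmax(ig, 1L)][dl < dr]
      lab[gap][dr < dl] <- lb[pmin(ig + 1L, length(st))][dr < dl]
      # dl == dr (midpoint tie): stays NA
    }
    out[q] <- lab
  }
  out
}

#' Infer missing founder STR genotypes by the modal-allele rule
#'
#' For each STR locus with a missing founder allele, strains are partitioned
#' by their inferred founder label at the locus (block containing the locus,
#' or nearest block for gap loci).  Within the label group of the missing
#' founder, homozygous non-missing genotypes are tallied: if at most one
#' non-modal ("de novo") value is present and the modal allele is carried by
#' a strict majority of the group's non-missing strains, the founder is
#' assigned the modal allele; otherwise the locus is dropped from downstream
#' analysis.  Groups with zero usable strains also drop.
#'
#' @param founders a \code{\linkS4class{FounderPanel}}.
#' @param strSE STR genotype experiment (assays \code{a1}, \code{a2}).
#' @param blocks haplotype blocks from \code{\link{buildHaplotypeBlocks}}.
#' @return list: \code{founders} (panel with resolved alleles),
#'   \code{droppedLoci} (character locus ids), \code{log} (per-inference
#'   decision table).
#' @export
inferMissingFounderStr <- function(founders, strSE, blocks) {
  st <- founders@strLoci
  a1 <- SummarizedExperiment::assay(strSE, "a1")
  a2 <- SummarizedExperiment::assay(strSE, "a2")
  strains <- colnames(a1)
  need <- which(is.na(st$ruB) | is.na(st$ruD))
  if (!length(need))
    return(list(founders = founders, droppedLoci = character(),
                log = data.frame()))
  chrom <- as.character(GenomeInfoDb::seqnames(st))[need]
  pos <- GenomicRanges::start(st)[need]
  labAt <- matrix(NA_character_, length(need), length(strains),
                  dimnames = list(st$locusId[need], strains))
  for (s in strains) labAt[, s] <- .blockLabelsAt(blocks, s, chrom, pos)
  ruB <- st$ruB; ruD <- st$ruD
  dropped <- character(); logs <- list()
  for (k in seq_along(need)) {
    l <- need[k]
    ok <- TRUE
    for (f in c("B", "D")) {
      cur <- if (f == "B") ruB[l] else ruD[l]
      if (!is.na(cur)) next
      grp <- strains[!is.na(labAt[k, ]) & labAt[k, ] == f]
      hom <- grp[!is.na(a1[l, grp]) & !is.na(a2[l, grp]) &
                   a1[l, grp] == a2[l, grp]]
      vals <- a1[l, hom]
      if (!length(vals)) { ok <- FALSE; break }
      tab <- sort(table(vals), decreasing = TRUE)
      modal <- as.integer(names(tab)[1])
      accept <- (length(tab) - 1L) <= 1L && tab[1] > length(vals) / 2
      logs[[length(logs) + 1L]] <- data.frame(
        locusId = st$locusId[l], founder = f,
        inferredRu = if (accept) modal else NA_integer_,
        nStrains = length(vals), nDistinct = length(tab),
        decision = if (accept) "inferred" else "dropped")
      if (!accept) { ok <- FALSE; break }
      if (f == "B") ruB[l] <- modal else ruD[l] <- modal
    }
    if (!ok) dropped <- c(dropped, st$locusId[l])
  }
  st$ruB <- ruB; st$ruD <- ruD
  out <- founders
  out@strLoci <- st
  list(founders = out, droppedLoci = dropped,
       log = if (length(logs)) do.call(rbind, logs) else data.frame())
}

#' Founder genotype probabilities for QTL mapping
#'
#' Extracts the HMM marginal posteriors as per-strain, per-marker founder
#' genotype probabilities P(B), P(D) = 1 - P(B).
#'
#' @param fls a \code{\linkS4class{FounderLabelSet}} with a \code{"probB"}
#'   assay (after \code{\link{imputeFounderLabels}}).
#' @return list: \code{pB} (strains x markers matrix), \code{marker},
#'   \code{chrom}, \code{posBp}, \code{cM}.
#' @export
founderGenoProb <- function(fls) {
  if (!"probB" %in% SummarizedExperiment::assayNames(fls))
    stop("run imputeFounderLabels() first (no 'probB' assay)")
  rr <- SummarizedExperiment::rowRanges(fls)
  list(pB = t(SummarizedExperiment::assay(fls, "probB")),
       marker = rownames(fls),
       chrom = as.character(GenomeInfoDb::seqnames(rr)),
       posBp = GenomicRanges::start(rr), cM = rr$cM)
}
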