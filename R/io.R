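#' Write / read the SNP genotype table and marker map
#'
#' The SNP table is a strains x markers TSV of founder-coded calls
#' (\code{B}, \code{H}, \code{D}, \code{NA}), with two extra rows
#' \code{founder_B} / \code{founder_D} carrying the founders' own coded
#' genotypes (\code{NA} at founder-uninformative markers, which is how
#' informativeness round-trips).  The marker map TSV has columns
#' \code{marker}, \code{chrom}, \code{pos_bp}, \code{pos_cM}.
#'
#' @param snp SNP \code{SummarizedExperiment} (assay \code{"geno"}).
#' @param path,mapPath output TSV paths.
#' @return (invisibly) the paths.
#' @export
writeSnpTable <- function(snp, path, mapPath) {
  geno <- SummarizedExperiment::assay(snp, "geno")
  rr <- SummarizedExperiment::rowRanges(snp)
  informative <- rr$alleleB != rr$alleleD
  fB <- ifelse(informative, "B", NA_character_)
  fD <- ifelse(informative, "D", NA_character_)
  tab <- rbind(t(geno), founder_B = fB, founder_D = fD)
  colnames(tab) <- rownames(geno)
  dt <- data.table::as.data.table(tab, keep.rownames = "strain_id")
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(data.table::data.table(
    marker = rownames(geno),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos_bp = GenomicRanges::start(rr), pos_cM = rr$cM),
    mapPath, sep = "\t", quote = FALSE)
  invisible(c(path, mapPath))
}

#' @rdname writeSnpTable
#' @return \code{readSnpTable}: a SNP \code{SummarizedExperiment} whose
#'   \code{rowRanges} carry reconstructed founder alleles (synthetic bases
#'   encoding informativeness) and cM positions.
#' @export
readSnpTable <- function(path, mapPath) {
  tab <- data.table::fread(path, sep = "\t", na.strings = "NA",
                           colClasses = "character")
  if (names(tab)[1] != "strain_id") stop("SNP table must start with strain_id")
  map <- data.table::fread(mapPath, sep = "\t")
  need <- c("marker", "chrom", "pos_bp", "pos_cM")
  if (!all(need %in% names(map)))
    stop("marker map must have columns ", paste(need, collapse = ", "))
  markers <- setdiff(names(tab), "strain_id")
  if (!all(markers %in% map$marker))
    stop("markers missing from map: ",
         paste(utils::head(setdiff(markers, map$marker), 3), collapse = ", "))
  map <- map[match(markers, map$marker), ]
  m <- as.matrix(tab[, -1]); rownames(m) <- tab$strain_id
  fRows <- c("founder_B", "founder_D")
  if (!all(fRows %in% rownames(m)))
    stop("SNP table must contain founder_B and founder_D rows")
  informative <- unname(!is.na(m["founder_B", ]))
  geno <- t(m[setdiff(rownames(m), fRows), , drop = FALSE])
  rr <- GenomicRanges::GRanges(map$chrom,
                               IRanges::IRanges(map$pos_bp, width = 1L),
                               alleleB = rep("A", nrow(map)),
                               alleleD = ifelse(informative, "G", "A"),
                               cM = map$pos_cM)
  names(rr) <- markers
  o <- order(match(as.character(GenomeInfoDb::seqnames(rr)),
                   unique(map$chrom)), GenomicRanges::start(rr))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno[o, , drop = FALSE]), rowRanges = rr[o],
    colData = S4Vectors::DataFrame(strainId = colnames(geno),
                                   row.names = colnames(geno)))
}

#' Read strain metadata
#'
#' @param path TSV with columns \code{strain_id}, \code{epoch},
#'   \code{n_generations}.
#' @return data.frame with \code{strainId}, \code{epoch},
#'   \code{nGenerations}.
#' @export
readMetadata <- function(path) {
  md <- data.table::fread(path, sep = "\t")
  need <- c("strain_id", "epoch", "n_generations")
  if (!all(need %in% names(md)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         " (missing: ", paste(setdiff(need, names(md)), collapse = ", "), ")")
  data.frame(strainId = as.character(md$strain_id),
             epoch = as.character(md$epoch),
             nGenerations = as.integer(md$n_generations))
}

# cross-file strain consistency check; errors naming the offenders
.checkStrains <- function(strains, metadataStrains, context) {
  extra <- setdiff(strains, metadataStrains)
  if (length(extra))
    stop("strains present in ", context, " but absent from metadata: ",
         paste(utils::head(extra, 5), collapse = ", "))
  invisible(TRUE)
}

#' Write / read STR genotypes as VCF 4.2
#'
#' One record per locus; INFO fields \code{RU} (motif), \code{END},
#' \code{BRU} / \code{DRU} (founder repeat-unit counts, \code{.} when the
#' founder is ungenotyped); FORMAT \code{GT} and \code{REPCN} (diploid
#' repeat copy numbers \code{"a,b"}).  Missing calls are \code{./.} with
#' \code{REPCN .}.  Positions are 1-based per VCF; the in-memory
#' representation uses the same 1-based convention (GRanges), so no
#' conversion is applied.
#'
#' @param strSE STR genotype experiment (assays \code{a1}, \code{a2}).
#' @param founders \code{\linkS4class{FounderPanel}} supplying motif and
#'   founder alleles.
#' @param path output VCF path.
#' @return (invisibly) \code{path}.
#' @export
writeStrVcf <- function(strSE, founders, path) {
  st <- founders@strLoci
  a1 <- SummarizedExperiment::assay(strSE, "a1")
  a2 <- SummarizedExperiment::assay(strSE, "a2")
  stopifnot(identical(rownames(a1), st$locusId))
  chrom <- as.character(GenomeInfoDb::seqnames(st))
  pos <- GenomicRanges::start(st)
  refRu <- ifelse(!is.na(st$ruB), st$ruB, st$ruD)
  if (anyNA(refRu)) stop("loci with both founder alleles missing cannot be written")
  n <- length(st)
  samples <- colnames(a1)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", GenomeInfoDb::seqlevels(st), ",length=",
                  GenomeInfoDb::seqlengths(st), ">"),
           "##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat motif\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of reference repeat tract\">",
           "##INFO=<ID=BRU,Number=1,Type=Integer,Description=\"B founder repeat copy number\">",
           "##INFO=<ID=DRU,Number=1,Type=Integer,Description=\"D founder repeat copy number\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=REPCN,Number=2,Type=Integer,Description=\"Diploid repeat copy numbers\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- character(n)
  naOr <- function(x) ifelse(is.na(x), ".", x)
  for (i in seq_len(n)) {
    g1 <- a1[i, ]; g2 <- a2[i, ]
    alleles <- sort(unique(stats::na.omit(c(refRu[i], g1, g2))))
    alleles <- c(refRu[i], setdiff(alleles, refRu[i]))
    alt <- if (length(alleles) > 1L)
      paste(vapply(alleles[-1], function(r) strrep(st$motif[i], r),
                   character(1)), collapse = ",") else "."
    i1 <- match(g1, alleles) - 1L; i2 <- match(g2, alleles) - 1L
    fld <- ifelse(is.na(g1), "./.:.",
                  paste0(i1, "/", i2, ":", g1, ",", g2))
    info <- paste0("RU=", st$motif[i],
                   ";END=", pos[i] + refRu[i] * st$motifLen[i] - 1L,
                   ";BRU=", naOr(st$ruB[i]), ";DRU=", naOr(st$ruD[i]))
    body[i] <- paste(c(chrom[i], pos[i], st$locusId[i],
                       strrep(st$motif[i], refRu[i]), alt, ".", "PASS",
                       info, "GT:REPCN", fld), collapse = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' @rdname writeStrVcf
#' @return \code{readStrVcf}: an STR \code{RangedSummarizedExperiment};
#'   \code{rowRanges} carry \code{locusId}, \code{motif}, \code{motifLen},
#'   \code{canonicalMotif}, \code{ruB}, \code{ruD}.
#' @export
readStrVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  info <- fix[, "INFO"]
  getInfo <- function(tag) {
    pat <- paste0("(^|;)", tag, "=[^;]*")
    has <- grepl(pat, info)
    if (!all(has))
      stop("VCF record missing INFO tag ", tag, ": ",
           fix[which(!has)[1], "ID"])
    sub(paste0(".*", tag, "="), "",
        regmatches(info, regexpr(pat, info)))
  }
  motif <- getInfo("RU")
  bru <- suppressWarnings(as.integer(getInfo("BRU")))
  dru <- suppressWarnings(as.integer(getInfo("DRU")))
  rep_ <- vcfR::extract.gt(v, element = "REPCN")
  if (is.null(rep_)) stop("VCF lacks a REPCN FORMAT field")
  a1 <- matrix(NA_integer_, nrow(rep_), ncol(rep_), dimnames = dimnames(rep_))
  a2 <- a1
  ok <- !is.na(rep_) & rep_ != "."
  parts <- strsplit(rep_[ok], ",", fixed = TRUE)
  a1[ok] <- as.integer(vapply(parts, `[`, character(1), 1L))
  a2[ok] <- as.integer(vapply(parts, `[`, character(1), 2L))
  ids <- fix[, "ID"]
  rownames(a1) <- rownames(a2) <- ids
  rr <- GenomicRanges::GRanges(fix[, "CHROM"],
                               IRanges::IRanges(as.integer(fix[, "POS"]),
                                                width = 1L),
                               locusId = ids, motif = motif,
                               motifLen = nchar(motif),
                               canonicalMotif = canonicalMotif(motif),
                               ruB = bru, ruD = dru)
  names(rr) <- ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(a1 = a1, a2 = a2), rowRanges = rr,
    colData = S4Vectors::DataFrame(strainId = colnames(a1),
                                   row.names = colnames(a1)))
}

#' Write / read haplotype blocks as BED-style TSV
#'
#' Five columns: \code{chrom}, \code{start} (0-based), \code{end}
#' (half-open), \code{strain}, \code{label}.  The in-memory blocks are
#' 1-based closed (GRanges); conversion happens only here.
#'
#' @param blocks blocks \code{GRanges} (\code{strain}, \code{label} mcols).
#' @param path output path.
#' @return (invisibly) \code{path}.
#' @export
writeBlocksBed <- function(blocks, path) {
  data.table::fwrite(data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(blocks)),
    start = GenomicRanges::start(blocks) - 1L,
    end = GenomicRanges::end(blocks),
    strain = blocks$strain, label = blocks$label),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBlocksBed
#' @return \code{readBlocksBed}: the blocks \code{GRanges}.
#' @export
readBlocksBed <- function(path) {
  b <- data.table::fread(path, sep = "\t",
                         col.names = c("chrom", "start", "end", "strain",
                                       "label"))
  GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end),
                         strain = as.character(b$strain),
                         label = as.character(b$label))
}

#' Assemble a founder panel from pipeline files
#'
#' Combines a SNP table + marker map (founder SNP alleles, cM map) with the
#' founder STR alleles carried in the STR VCF INFO fields.
#'
#' @param snp SNP experiment from \code{\link{readSnpTable}}.
#' @param strSE STR experiment from \code{\link{readStrVcf}}.
#' @return a \code{\linkS4class{FounderPanel}}.
#' @export
assembleFounderPanel <- function(snp, strSE) {
  methods::new("FounderPanel",
               markers = SummarizedExperiment::rowRanges(snp),
               strLoci = SummarizedExperiment::rowRanges(strSE))
}

#' Run manifest utilities
#'
#' A manifest records the resolved configuration, seeds, input checksums
#' and per-stage record counts (input = retained + dropped per reason);
#' \code{validateManifest} asserts that the counts reconcile.
#'
#' @param config resolved configuration list.
#' @param seed integer seed of the run.
#' @return \code{newManifest}: a manifest list.
#' @export
newManifest <- function(config, seed) {
  list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       seed = seed, config = config, inputs = list(), stages = list())
}

#' @rdname newManifest
#' @param manifest a manifest list.
#' @param paths named character vector of input files to checksum.
#' @export
addManifestInputs <- function(manifest, paths) {
  for (nm in names(paths))
    manifest$inputs[[nm]] <- list(path = unname(paths[[nm]]),
                                  md5 = unname(tools::md5sum(paths[[nm]])))
  manifest
}

#' @rdname newManifest
#' @param stage stage name.
#' @param input number of input records.
#' @param retained number retained.
#' @param dropped named list/vector of dropped counts per reason.
#' @export
addManifestStage <- function(manifest, stage, input, retained,
                             dropped = list()) {
  manifest$stages[[stage]] <- list(input = input, retained = retained,
                                   dropped = as.list(dropped))
  manifest
}

#' @rdname newManifest
#' @export
validateManifest <- function(manifest) {
  for (nm in names(manifest$stages)) {
    st <- manifest$stages[[nm]]
    total <- st$retained + sum(unlist(st$dropped))
    if (!isTRUE(all.equal(st$input, total)))
      stop("manifest stage '", nm, "' does not reconcile: input ", st$input,
           " != retained ", st$retained, " + dropped ",
           sum(unlist(st$dropped)))
  }
  invisible(TRUE)
}

#' @rdname newManifest
#' @param path output JSON path.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
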