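# On-disk formats. External formats (BED, VCF) are 0-/1-based per their
# specifications; internally everything is a GRanges (1-based closed). The
# conversion happens here and only here.

.parseTags <- function(x) {
  # "k1=v1;k2=v2" name fields -> list of named character vectors
  lapply(strsplit(x, ";", fixed = TRUE), function(parts) {
    parts <- parts[nzchar(parts) & parts != "."]
    kv <- strsplit(parts, "=", fixed = TRUE)
    ok <- lengths(kv) == 2L
    structure(vapply(kv[ok], `[`, character(1), 2L),
              names = vapply(kv[ok], `[`, character(1), 1L))
  })
}

.tagField <- function(tags, key) {
  vapply(tags, function(t) if (key %in% names(t)) t[[key]] else NA_character_,
         character(1))
}

.readBed6 <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0) stop("empty BED file: ", path, call. = FALSE)
  bad <- which(is.na(nf) | nf < 6L)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s (expected 6 tab-separated fields)",
                 bad[1], path), call. = FALSE)
  d <- read.table(path, sep = "\t", quote = "", comment.char = "",
                  colClasses = c("character", "numeric", "numeric",
                                 "character", "character", "character"),
                  col.names = c("chrom", "start", "end", "name", "score",
                                "strand"))
  badc <- which(d$start < 0 | d$end <= d$start)
  if (length(badc))
    stop(sprintf("BED line %d: start/end invalid (need 0 <= start < end)",
                 badc[1]), call. = FALSE)
  d
}

#' Read / write strand-specific ssDNA fragments as BED6
#'
#' Fragments are BED6 with 0-based half-open intervals and a mandatory
#' strand (`+`/`-`; SSDS fragments are strand-resolved by construction, so
#' `.` is rejected). The name field optionally carries `key=value;` truth
#' tags written by the simulator: `id`, `hap` (B6/CAST/background), `role`
#' (dsb_initiating/repair_template/h3k4me3/background), `hs` (hotspot id),
#' `brk` (0-based true break coordinate).
#'
#' @param path file path.
#' @return `readFragmentsBed`: a `GRanges` with strand and metadata columns
#'   `fragmentId`, `truthHaplotype`, `truthRole`, `truthHotspot`,
#'   `truthBreak` (1-based internal coordinate or NA).
#' @export
readFragmentsBed <- function(path) {
  d <- .readBed6(path)
  badStrand <- which(!d$strand %in% c("+", "-"))
  if (length(badStrand))
    stop(sprintf("BED line %d: strand '%s' invalid (SSDS fragments require + or -)",
                 badStrand[1], d$strand[badStrand[1]]), call. = FALSE)
  tags <- .parseTags(d$name)
  id <- .tagField(tags, "id")
  noId <- is.na(id)
  id[noId] <- ifelse(d$name[noId] %in% c("", "."),
                     sprintf("frag%07d", which(noId)), d$name[noId])
  brk <- suppressWarnings(as.numeric(.tagField(tags, "brk")))
  GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(start = d$start + 1, end = d$end),
    strand = d$strand,
    fragmentId = id,
    truthHaplotype = .tagField(tags, "hap"),
    truthRole = .tagField(tags, "role"),
    truthHotspot = .tagField(tags, "hs"),
    truthBreak = brk + 1)
}

#' @rdname readFragmentsBed
#' @param fragments a fragments `GRanges` as returned by
#'   [simulateFragments()] or `readFragmentsBed`.
#' @export
writeFragmentsBed <- function(fragments, path) {
  mc <- S4Vectors::mcols(fragments)
  tag <- function(key, val) ifelse(is.na(val), "", sprintf("%s=%s;", key, val))
  if (!is.null(mc$truthBreak)) {
    brk0 <- rep(NA_character_, length(fragments))
    ok <- !is.na(mc$truthBreak)
    brk0[ok] <- .fmtNum(mc$truthBreak[ok] - 1)
  } else {
    brk0 <- rep(NA_character_, length(fragments))
  }
  name <- paste0(tag("id", mc$fragmentId),
                 tag("hap", mc$truthHaplotype),
                 tag("role", mc$truthRole),
                 tag("hs", mc$truthHotspot),
                 tag("brk", brk0))
  name <- sub(";$", "", name)
  name[!nzchar(name)] <- "."
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(fragments)),
                  start = BiocGenerics::start(fragments) - 1,
                  end = BiocGenerics::end(fragments),
                  name = name, score = 0,
                  strand = as.character(BiocGenerics::strand(fragments)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write hotspots as BED6
#'
#' BED6 whose score column carries the hotspot heat, strand the orientation,
#' and name field `id=..;center=<0-based>;f=..;class=..;xnp=0|1` tags (the
#' on-disk center convention is this package's own).
#'
#' @param path file path.
#' @return `readHotspotsBed`: a hotspot `GRanges` (see [makeHotspots()]).
#' @export
readHotspotsBed <- function(path) {
  d <- .readBed6(path)
  badStrand <- which(!d$strand %in% c("+", "-"))
  if (length(badStrand))
    stop(sprintf("BED line %d: hotspot orientation must be + or -",
                 badStrand[1]), call. = FALSE)
  tags <- .parseTags(d$name)
  center0 <- as.numeric(.tagField(tags, "center"))
  if (anyNA(center0))
    stop("hotspot BED requires a 'center=' tag in the name field",
         call. = FALSE)
  makeHotspots(chrom = d$chrom, start = d$start + 1, end = d$end,
               center = center0 + 1, heat = as.numeric(d$score),
               fTrue = as.numeric(.tagField(tags, "f")),
               orientation = d$strand,
               prdm9Class = .tagField(tags, "class"),
               onXNonPar = .tagField(tags, "xnp") == "1",
               hotspotId = .tagField(tags, "id"))
}

#' @rdname readHotspotsBed
#' @param hotspots hotspot `GRanges`.
#' @export
writeHotspotsBed <- function(hotspots, path) {
  .checkHotspots(hotspots)
  mc <- S4Vectors::mcols(hotspots)
  name <- sprintf("id=%s;center=%s;f=%s;class=%s;xnp=%d",
                  mc$hotspotId, .fmtNum(mc$center - 1), .fmtNum(mc$fTrue),
                  mc$prdm9Class, as.integer(mc$onXNonPar))
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(hotspots)),
                  start = BiocGenerics::start(hotspots) - 1,
                  end = BiocGenerics::end(hotspots),
                  name = name, score = .fmtNum(mc$heat),
                  strand = as.character(BiocGenerics::strand(hotspots)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a SNP table (VCF or TSV dialect)
#'
#' Auto-detects the dialect from the header: a `##fileformat=VCF` line means
#' VCF (biallelic SNVs; REF is taken as the B6 allele, ALT as CAST; VCF POS
#' is 1-based and converted internally), otherwise a 4-column TSV with
#' header `chrom  pos  b6  cast` and 0-based positions. Indel/multiallelic
#' VCF records are skipped with a warning carrying the count; a duplicated
#' position is an error.
#'
#' @param path file path.
#' @return `GRanges` of width-1 SNPs with `b6`/`cast` metadata columns.
#' @export
readSnps <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "sim"))
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    nAlt <- lengths(altL)
    alt1 <- rep(NA_character_, length(rr))
    alt1[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
    keep <- nAlt == 1L & nchar(ref) == 1L & !is.na(alt1) &
      nchar(alt1) == 1L & ref %in% c("A", "C", "G", "T") &
      alt1 %in% c("A", "C", "G", "T")
    if (any(!keep))
      warning(sum(!keep), " non-SNV VCF record(s) skipped", call. = FALSE)
    gr <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(rr)[keep],
      IRanges::IRanges(start = BiocGenerics::start(rr)[keep], width = 1L),
      b6 = ref[keep], cast = alt1[keep])
  } else {
    d <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", colClasses = c("character", "numeric",
                                                      "character", "character"))
    if (!identical(names(d), c("chrom", "pos", "b6", "cast")))
      stop("SNP TSV must have header: chrom pos b6 cast", call. = FALSE)
    gr <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(start = d$pos + 1, width = 1L),
      b6 = d$b6, cast = d$cast)
  }
  key <- paste(GenomeInfoDb::seqnames(gr), BiocGenerics::start(gr))
  if (anyDuplicated(key))
    stop("duplicate SNP position: ", key[anyDuplicated(key)], call. = FALSE)
  BiocGenerics::sort(gr)
}

#' @rdname readSnps
#' @param snps SNP `GRanges`.
#' @export
writeSnpsTsv <- function(snps, path) {
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(snps)),
                  pos = BiocGenerics::start(snps) - 1,
                  b6 = S4Vectors::mcols(snps)$b6,
                  cast = S4Vectors::mcols(snps)$cast)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readMetaTsv <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in metaLines) {
    kv <- strsplit(sub("^# ", "", ml), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  d <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                  header = TRUE, quote = "", comment.char = "")
  list(meta = meta, table = d)
}

#' Read / write aggregate profiles as long-format TSV
#'
#' Serialized as `strand  role  bin_start  value` rows preceded by
#' `# key=value` metadata lines, chosen for diff-ability.
#'
#' @param path file path.
#' @return `readProfileTsv`: a [StrandProfile-class].
#' @export
readProfileTsv <- function(path) {
  x <- .readMetaTsv(path)
  binsize <- as.integer(x$meta$binsize)
  halfWidth <- as.integer(x$meta$half_width)
  nb <- 2L * halfWidth %/% binsize
  vals <- matrix(0, nb, 4L,
                 dimnames = list(NULL, .panelNames))
  panel <- paste(x$table$strand, x$table$role, sep = ".")
  idx <- (x$table$bin_start + halfWidth) %/% binsize + 1L
  vals[cbind(idx, match(panel, .panelNames))] <- x$table$value
  new("StrandProfile", binsize = binsize, halfWidth = halfWidth,
      values = vals, nHotspots = as.integer(x$meta$n_hotspots),
      nFragments = as.integer(x$meta$n_fragments))
}

#' @rdname readProfileTsv
#' @param profile a [StrandProfile-class].
#' @export
writeProfileTsv <- function(profile, path) {
  bs <- binStarts(profile)
  v <- profileValues(profile)
  panels <- strsplit(colnames(v), ".", fixed = TRUE)
  d <- data.frame(
    strand = rep(vapply(panels, `[`, character(1), 1L), each = nrow(v)),
    role = rep(vapply(panels, `[`, character(1), 2L), each = nrow(v)),
    bin_start = rep(bs, times = ncol(v)),
    value = .fmtNum(as.vector(v)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# binsize=%d", profile@binsize),
               sprintf("# half_width=%d", profile@halfWidth),
               sprintf("# n_hotspots=%d", profile@nHotspots),
               sprintf("# n_fragments=%d", profile@nFragments)), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write deconvolved footprints as long-format TSV
#'
#' Same long format as profiles, plus per-panel residual norms and the ridge
#' penalty in the metadata lines.
#'
#' @param path file path.
#' @return `readFootprintTsv`: a [FootprintModel-class].
#' @export
readFootprintTsv <- function(path) {
  x <- .readMetaTsv(path)
  binsize <- as.integer(x$meta$binsize)
  halfWidth <- as.integer(x$meta$half_width)
  nb <- 2L * halfWidth %/% binsize
  panel <- paste(x$table$strand, x$table$role, sep = ".")
  panels <- unique(panel)
  vals <- matrix(0, nb, length(panels), dimnames = list(NULL, panels))
  idx <- (x$table$bin_start + halfWidth) %/% binsize + 1L
  vals[cbind(idx, match(panel, panels))] <- x$table$value
  res <- vapply(panels, function(p)
    as.numeric(x$meta[[paste0("residual.", p)]]), numeric(1))
  new("FootprintModel", values = vals, residuals = res,
      lambda = as.numeric(x$meta$lambda), binsize = binsize,
      halfWidth = halfWidth)
}

#' @rdname readFootprintTsv
#' @param footprint a [FootprintModel-class].
#' @export
writeFootprintTsv <- function(footprint, path) {
  bs <- binStarts(footprint)
  v <- footprintValues(footprint)
  panels <- strsplit(colnames(v), ".", fixed = TRUE)
  d <- data.frame(
    strand = rep(vapply(panels, `[`, character(1), 1L), each = nrow(v)),
    role = rep(vapply(panels, `[`, character(1), 2L), each = nrow(v)),
    bin_start = rep(bs, times = ncol(v)),
    value = .fmtNum(as.vector(v)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# binsize=%d", footprint@binsize),
               sprintf("# half_width=%d", footprint@halfWidth),
               sprintf("# lambda=%s", .fmtNum(footprint@lambda)),
               sprintf("# residual.%s=%s", colnames(v),
                       .fmtNum(footprint@residuals))), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
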