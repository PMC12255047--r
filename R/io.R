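#' File interfaces
#'
#' Cohorts travel as phased GT-only VCF; local-ancestry tracks as an
#' RFMix-msp-style tab-separated table (one row per interval on which every
#' haplotype's ancestry is constant, then one ancestry code per haplotype);
#' summary statistics as plain TSV. Readers are strict about the subset of
#' each format the package writes and report the offending line number.
#'
#' @name workflow_io
NULL

#' Write a phased VCF from a haplotype matrix
#'
#' @param hap 2n x m 0/1 haplotype matrix (consecutive row pairs are one
#'   individual).
#' @param map `genetic_map` giving 0-based bp positions (written 1-based).
#' @param path output file.
#' @param chrom contig name.
#' @param sample_prefix sample name prefix.
#' @export
write_vcf <- function(hap, map, path, chrom = "1", sample_prefix = "ind") {
  n <- nrow(hap) %/% 2L
  m <- ncol(hap)
  samples <- paste0(sample_prefix, seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom,
            as.integer(max(map$bp)) + 1L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  i1 <- seq(1, 2 * n, 2)
  for (k in seq_len(m)) {
    gt <- paste(hap[i1, k], hap[i1 + 1L, k], sep = "|")
    writeLines(paste(c(chrom, as.integer(map$bp[k]) + 1L,
                       paste0("snp", k), "A", "T", ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phased GT-only VCF back into a haplotype matrix
#'
#' Strict reader for the subset written by [write_vcf()]: diploid, phased,
#' GT-only records with strictly increasing positions.
#'
#' @param path VCF file.
#' @return list(hap, bp (0-based), samples, chrom).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("line 1: missing ##fileformat header")
  }
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1) stop("malformed header: expected one #CHROM line")
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(fields) < 10) stop("line ", hdr, ": no sample columns")
  samples <- fields[-(1:9)]
  n <- length(samples)
  body <- lines[-seq_len(hdr)]
  hap <- matrix(0L, 2L * n, length(body))
  bp <- integer(length(body))
  chrom <- NA_character_
  for (r in seq_along(body)) {
    ln <- hdr + r
    f <- strsplit(body[r], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 + n) stop("line ", ln, ": wrong number of fields")
    if (f[9] != "GT") stop("line ", ln, ": FORMAT must be GT")
    chrom <- f[1]
    bp[r] <- as.integer(f[2]) - 1L
    gt <- f[-(1:9)]
    bad <- !grepl("^[01]\\|[01]$", gt)
    if (any(bad)) {
      stop("line ", ln, ": unphased or non-diploid GT in sample ",
           which(bad)[1])
    }
    hap[seq(1, 2 * n, 2), r] <- as.integer(substr(gt, 1, 1))
    hap[seq(2, 2 * n, 2), r] <- as.integer(substr(gt, 3, 3))
  }
  if (any(diff(bp) <= 0)) {
    stop("line ", hdr + which(diff(bp) <= 0)[1] + 1L,
         ": positions not strictly increasing")
  }
  list(hap = hap, bp = bp, samples = samples, chrom = chrom)
}

#' Write a local-ancestry track in msp-style TSV
#'
#' Columns: chm, spos, epos (0-based bp, half-open), sgpos, egpos (cM),
#' n_snps, then one ancestry code per haplotype. Rows are the maximal
#' intervals on which every haplotype's ancestry is constant.
#'
#' @param pop an `admixed_population`.
#' @param path output file.
#' @param chrom contig name.
#' @export
write_msp <- function(pop, path, chrom = "1") {
  anc <- pop$anc
  m <- ncol(anc)
  change <- if (m > 1) {
    which(colSums(anc[, -1, drop = FALSE] != anc[, -m, drop = FALSE]) > 0)
  } else integer(0)
  starts <- c(1L, change + 1L)
  ends <- c(change, m)
  cm <- pop$map$morgans * 100
  hap_cols <- t(anc[, starts, drop = FALSE])
  colnames(hap_cols) <- paste0("hap", seq_len(nrow(anc)))
  df <- data.frame(chm = chrom, spos = pop$map$bp[starts],
                   epos = c(pop$map$bp[starts[-1]], max(pop$map$bp) + 1),
                   sgpos = cm[starts], egpos = c(cm[starts[-1]], max(cm)),
                   n_snps = ends - starts + 1L)
  df <- cbind(df, hap_cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an msp-style local-ancestry TSV
#'
#' @param path file written by [write_msp()].
#' @return data.frame; haplotype columns are `hap1..hap2n`.
#' @export
read_msp <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("chm", "spos", "epos", "sgpos", "egpos", "n_snps")
  if (!all(need %in% names(df))) {
    stop("line 1: missing msp columns ",
         paste(setdiff(need, names(df)), collapse = ","))
  }
  if (sum(grepl("^hap", names(df))) %% 2 != 0) {
    stop("haplotype columns must come in pairs (2 per individual)")
  }
  df
}

#' Write / read a summary-statistics TSV
#'
#' @param sumstats data.frame (e.g. from [tractor_scan()]).
#' @param path file path.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) utils::read.delim(path)

#' Echo a run configuration as a structured text manifest
#'
#' One `key: value` line per scalar entry; nested lists are indented.
#' Re-running an experiment from the same manifest reproduces its outputs.
#'
#' @param config named list.
#' @param path output file.
#' @export
write_manifest <- function(config, path) {
  emit <- function(x, indent) {
    unlist(lapply(names(x), function(nm) {
      v <- x[[nm]]
      if (is.list(v)) {
        c(paste0(indent, nm, ":"), emit(v, paste0(indent, "  ")))
      } else {
        paste0(indent, nm, ": ", paste(v, collapse = " "))
      }
    }))
  }
  writeLines(emit(config, ""), path)
  invisible(path)
}
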