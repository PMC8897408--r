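# Shared readers/writers: FASTA (Biostrings), VCF (text emitter + vcfR
# reader), the pileup TSV dialect, BED/TSV, newick (ape), population maps and
# YAML run configs. Coordinates are 0-based half-open internally and in BED,
# 1-based in VCF, TSV reports and the pileup dialect.

#' Write named sequences as FASTA
#' @param seqs named character vector (IUPAC codes allowed).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a pileup set in the package's TSV dialect
#'
#' One row per observed base: contig, pos (1-based), individual, base, phred,
#' strand, offset5, offset3. Count-derived pileups (no per-read provenance)
#' write strand "." and offsets -1.
#'
#' @param pileups a `pileup_set`.
#' @param path output TSV.
#' @export
write_pileup_tsv <- function(pileups, path) {
  cnt <- pileups$counts
  idx <- which(cnt > 0, arr.ind = TRUE)
  n <- cnt[idx]
  rows <- data.frame(contig = rep(pileups$contig[idx[, 1]], n),
                     pos = rep(pileups$pos[idx[, 1]], n),
                     individual = rep(pileups$individuals[idx[, 2]], n),
                     base = rep(BASES[idx[, 3]], n),
                     phred = pileups$qual,
                     strand = ".", offset5 = -1L, offset3 = -1L)
  rows <- rows[order(rows$contig, rows$pos, rows$individual), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the pileup TSV dialect back into a `pileup_set`
#' @param path TSV written by [write_pileup_tsv()] (or compatible).
#' @export
read_pileup_tsv <- function(path) {
  rows <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  key <- paste(rows$contig, rows$pos)
  ukey <- unique(key[order(rows$contig, rows$pos)])
  site <- match(key, ukey)
  individuals <- sort(unique(rows$individual))
  ind <- match(rows$individual, individuals)
  bidx <- match(rows$base, BASES)
  counts <- array(0L, dim = c(length(ukey), length(individuals), 4),
                  dimnames = list(NULL, individuals, BASES))
  tab <- tabulate((site - 1L) * (length(individuals) * 4L) + (ind - 1L) * 4L + bidx,
                  nbins = length(ukey) * length(individuals) * 4L)
  counts[] <- aperm(array(tab, dim = c(4, length(individuals), length(ukey))),
                    c(3, 2, 1))
  first <- !duplicated(site)
  structure(list(contig = rows$contig[first][order(site[first])],
                 pos = rows$pos[first][order(site[first])],
                 individuals = individuals, counts = counts,
                 depth = apply(counts, c(1, 2), sum),
                 qual = rows$phred[1], depth_tracks = NULL,
                 contigs = unique(rows$contig), window_length = NA),
            class = "pileup_set")
}

#' Write a site table as a multi-sample VCF
#'
#' Emits GT (hard calls; ./. for missing), PL (phred-scaled likelihoods) and
#' DP per individual. FILTER lists the failed site-level flags (missing, maf,
#' triallelic) or PASS; per-individual low/high depth shows up as missing
#' genotypes. Positions are 1-based.
#'
#' @param site_table a filtered `site_table`.
#' @param path output VCF (plain text).
#' @param contig_lengths optional named lengths for the header.
#' @export
write_site_table_vcf <- function(site_table, path, contig_lengths = NULL) {
  st <- site_table
  s <- st$sites
  n_ind <- length(st$individuals)
  dosage <- hard_call(st, st$config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=museopop",
               "##FILTER=<ID=missing,Description=\"More individuals missing than allowed\">",
               "##FILTER=<ID=maf,Description=\"Minor allele frequency below threshold\">",
               "##FILTER=<ID=triallelic,Description=\"Significant third allele\">",
               "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"ML minor allele frequency\">",
               "##INFO=<ID=PSNP,Number=1,Type=Float,Description=\"SNP LRT p-value\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"), con)
  if (!is.null(contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", st$individuals), collapse = "\t"), con)
  if (nrow(s)) {
    filter_str <- rep("PASS", nrow(s))
    if (!is.null(s$pass)) {
      parts <- cbind(ifelse(s$flag_missing, "missing", NA),
                     ifelse(s$flag_maf, "maf", NA),
                     ifelse(s$flag_triallelic, "triallelic", NA))
      filter_str <- apply(parts, 1, function(p) {
        p <- p[!is.na(p)]
        if (length(p)) paste(p, collapse = ";") else "PASS"
      })
    }
    gt <- matrix("./.", nrow(s), n_ind)
    gt[!is.na(dosage) & dosage == 0L] <- "0/0"
    gt[!is.na(dosage) & dosage == 1L] <- "0/1"
    gt[!is.na(dosage) & dosage == 2L] <- "1/1"
    pl <- vapply(seq_len(nrow(s)), function(i) {
      tri <- round(-10 * st$gl[i, , , drop = FALSE])
      dim(tri) <- c(n_ind, 3)
      ifelse(is.na(tri[, 1]), ".",
             paste(tri[, 1], tri[, 2], tri[, 3], sep = ","))
    }, character(n_ind))
    dim(pl) <- c(n_ind, nrow(s))
    sample_cols <- vapply(seq_len(nrow(s)), function(i) {
      paste(paste(gt[i, ], pl[, i], st$depth[i, ], sep = ":"), collapse = "\t")
    }, character(1))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tMAF=%.6g;PSNP=%.3g\tGT:PL:DP\t%s",
                       s$contig, s$pos, s$major, s$minor, filter_str,
                       s$maf, s$p_snp, sample_cols), con)
  }
  invisible(path)
}

#' Read a multi-sample VCF into a `site_table`
#'
#' Honors GT (dosage of the ALT allele) and PL (converted back to normalized
#' log10 likelihoods); DP fills the depth matrix when present.
#'
#' @param path VCF file.
#' @return a `site_table` (unfiltered flags; `maf`/`f_minor` from INFO MAF
#'   when present, else from GT counts).
#' @export
read_vcf_site_table <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  individuals <- colnames(v@gt)[-1]
  n_site <- nrow(fix); n_ind <- length(individuals)
  gt <- vcfR::extract.gt(v, "GT")
  pl <- tryCatch(vcfR::extract.gt(v, "PL"), error = function(e) NULL)
  dp <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE), error = function(e) NULL)
  gl <- array(NA_real_, dim = c(n_site, n_ind, 3),
              dimnames = list(NULL, individuals, c("hom_major", "het", "hom_minor")))
  if (!is.null(pl)) {
    for (j in seq_len(n_ind)) {
      parts <- strsplit(ifelse(is.na(pl[, j]), "NA,NA,NA", pl[, j]), ",")
      m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3, byrow = TRUE)
      m <- -m / 10
      m <- m - apply(m, 1, max)
      gl[, j, ] <- m
    }
  }
  dosage <- matrix(NA_integer_, n_site, n_ind)
  dosage[gt == "0/0" | gt == "0|0"] <- 0L
  dosage[gt == "0/1" | gt == "1/0" | gt == "0|1" | gt == "1|0"] <- 1L
  dosage[gt == "1/1" | gt == "1|1"] <- 2L
  info_maf <- suppressWarnings(as.numeric(sub(".*MAF=([0-9.eE+-]+).*", "\\1",
                                              fix[, "INFO"])))
  cnt_f <- rowSums(dosage, na.rm = TRUE) / (2 * pmax(rowSums(!is.na(dosage)), 1))
  f_minor <- ifelse(is.na(info_maf), cnt_f, info_maf)
  sites <- data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      major = fix[, "REF"], minor = fix[, "ALT"],
                      maf = pmin(f_minor, 1 - f_minor), f_minor = f_minor,
                      p_snp = NA_real_, p_tri = NA_real_, triallelic = FALSE,
                      stringsAsFactors = FALSE)
  depth <- if (!is.null(dp)) {
    d <- dp; d[is.na(d)] <- 0; dimnames(d) <- list(NULL, individuals); d
  } else {
    matrix(NA_real_, n_site, n_ind, dimnames = list(NULL, individuals))
  }
  structure(list(sites = sites, gl = gl, depth = depth,
                 individuals = individuals, filtered = FALSE,
                 config = filter_config(), dosage = dosage),
            class = "site_table")
}

#' Read a two-column population map (individual, taxon)
#'
#' Duplicate individuals and empty files are errors; taxa keep file order.
#'
#' @param path TSV with two columns, no header required (a header line
#'   "individual<TAB>taxon" is tolerated).
#' @return named character vector individual -> taxon, with attribute `taxa`.
#' @export
read_population_map <- function(path) {
  rows <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, col.names = c("individual", "taxon"))
  if (nrow(rows) && rows$individual[1] == "individual") rows <- rows[-1, , drop = FALSE]
  if (!nrow(rows)) stop("population map is empty: ", path)
  dup <- rows$individual[duplicated(rows$individual)]
  if (length(dup)) stop("duplicated individual id(s): ", paste(unique(dup), collapse = ", "))
  map <- stats::setNames(rows$taxon, rows$individual)
  attr(map, "taxa") <- unique(rows$taxon)
  map
}

#' Write windows/intervals as BED (0-based half-open)
#' @param df data.frame with contig, start, end and optional further columns.
#' @param path output BED.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV with header
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
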