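#' Extract strand-aware upstream promoter windows
#'
#' For each annotated gene, the window of `window_bp` bases immediately
#' upstream of its start: `[start - window_bp, start - 1]` for plus-strand
#' genes and `[end + 1, end + window_bp]` for minus-strand genes, truncated
#' at chromosome ends (all coordinates 1-based, closed). Genes whose window
#' is fully truncated away are emitted with `length_bp = 0` and a warning;
#' downstream analyses skip them.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+` or `-`), 1-based closed intervals
#' @param chrom_lengths named numeric vector of chromosome lengths
#' @param window_bp window size in bases (default 1000)
#' @return data.frame with columns `gene_id`, `chrom`, `win_start`,
#'   `win_end`, `strand`, `length_bp`, `gene_start`, `gene_end`
#' @export
extract_promoter_windows <- function(genes, chrom_lengths, window_bp = 1000) {
  .assert(window_bp >= 1, "window_bp must be >= 1")
  .assert(all(c("gene_id", "chrom", "start", "end", "strand") %in%
              names(genes)), "gene table is missing required columns")
  .assert(!anyDuplicated(genes$gene_id), "gene_id values must be unique")
  .assert(all(genes$strand %in% c("+", "-")), "strand must be + or -")
  .assert(all(genes$chrom %in% names(chrom_lengths)),
          "every gene chromosome needs a length")
  len <- unname(chrom_lengths[genes$chrom])
  .assert(all(genes$start >= 1 & genes$start <= genes$end &
              genes$end <= len),
          "gene coordinates must satisfy 1 <= start <= end <= chrom length")
  plus <- genes$strand == "+"
  ws <- ifelse(plus, pmax(1, genes$start - window_bp), genes$end + 1)
  we <- ifelse(plus, genes$start - 1, pmin(len, genes$end + window_bp))
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    win_start = ws, win_end = we, strand = genes$strand,
                    length_bp = pmax(0L, we - ws + 1),
                    gene_start = genes$start, gene_end = genes$end)
  # windows overlapping neighbouring genes are kept untrimmed, but the
  # overlap is reported for transparency
  out$gene_overlap_bp <- 0L
  for (ch in unique(out$chrom)) {
    wi <- which(out$chrom == ch & out$length_bp > 0)
    if (length(wi) == 0) next
    gr <- IRanges::reduce(IRanges::IRanges(genes$start[genes$chrom == ch],
                                           genes$end[genes$chrom == ch]))
    wr <- IRanges::IRanges(out$win_start[wi], out$win_end[wi])
    ov <- IRanges::findOverlaps(wr, gr)
    if (length(ov) > 0) {
      shared <- IRanges::width(IRanges::pintersect(
        wr[S4Vectors::queryHits(ov)], gr[S4Vectors::subjectHits(ov)]))
      agg <- tapply(shared, S4Vectors::queryHits(ov), sum)
      out$gene_overlap_bp[wi[as.integer(names(agg))]] <- as.integer(agg)
    }
  }
  if (any(out$length_bp == 0)) {
    warning(sum(out$length_bp == 0), " gene(s) have zero-length promoter ",
            "windows (gene abuts the chromosome end) and will be skipped")
  }
  out
}

#' Maximal SNP-free conserved regions of one promoter window
#'
#' Conserved regions (CRs) are the maximal runs of window positions that
#' carry no segregating variant: the intervals between consecutive variant
#' positions, clipped to the window. Adjacent variants produce no CR; a
#' window free of variants yields a single CR spanning the whole window.
#' Computed by interval arithmetic on the sorted variant positions.
#'
#' @param win_start,win_end window bounds, 1-based closed
#' @param variant_pos sorted vector of variant positions on the window's
#'   chromosome (positions outside the window are ignored)
#' @return data.frame with columns `start`, `end`, `length_bp`
#' @export
find_conserved_regions <- function(win_start, win_end, variant_pos) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length_bp = integer(0))
  if (win_end < win_start) return(empty)
  v <- variant_pos[variant_pos >= win_start & variant_pos <= win_end]
  v <- unique(sort(v))
  starts <- c(win_start, v + 1)
  ends <- c(v - 1, win_end)
  keep <- ends >= starts
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]),
             length_bp = as.integer(ends[keep] - starts[keep] + 1))
}

# independent per-base oracle: mark every window base, scan runs with rle.
# used to build synthetic ground truth; deliberately a different code path
# from the interval arithmetic of find_conserved_regions.
.crs_bruteforce <- function(win_start, win_end, variant_pos) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length_bp = integer(0))
  if (win_end < win_start) return(empty)
  free <- rep(TRUE, win_end - win_start + 1)
  v <- variant_pos[variant_pos >= win_start & variant_pos <= win_end]
  free[v - win_start + 1] <- FALSE
  r <- rle(free)
  ends_rel <- cumsum(r$lengths)
  starts_rel <- ends_rel - r$lengths + 1
  keep <- r$values
  data.frame(start = as.integer(win_start + starts_rel[keep] - 1),
             end = as.integer(win_start + ends_rel[keep] - 1),
             length_bp = as.integer(r$lengths[keep]))
}

#' Signed offset of a conserved region from its gene's start
#'
#' Strand-aware distance from the annotated gene start to the CR midpoint:
#' 0 at the gene start, negative upstream, so promoter CRs have offsets in
#' `[-window_bp, 0)`. The midpoint of an even-length CR is rounded toward
#' the gene.
#'
#' @param cr_start,cr_end CR bounds, 1-based closed
#' @param gene_start,gene_end gene bounds
#' @param strand `"+"` or `"-"` (vectorised)
#' @return integer offsets in base pairs
#' @export
cr_offset <- function(cr_start, cr_end, gene_start, gene_end, strand) {
  mid <- (cr_start + cr_end) / 2
  plus <- rep_len(strand == "+", length(mid))
  gene_start <- rep_len(gene_start, length(mid))
  gene_end <- rep_len(gene_end, length(mid))
  # round toward the gene: up on +, down on -
  mid_r <- ifelse(plus, ceiling(mid), floor(mid))
  as.integer(ifelse(plus, mid_r - gene_start, gene_end - mid_r))
}

#' Conserved regions for a set of promoter windows
#'
#' Runs [find_conserved_regions()] on every non-degenerate window and
#' annotates each CR with its strand-aware offset from the gene start.
#'
#' @param windows window table from [extract_promoter_windows()]
#' @param variants_by_chrom named list of sorted variant position vectors,
#'   one per chromosome (as from [read_variant_positions()])
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `length_bp`, `offset_bp`
#' @export
conserved_regions <- function(windows, variants_by_chrom) {
  rows <- lapply(which(windows$length_bp > 0), function(i) {
    w <- windows[i, ]
    v <- variants_by_chrom[[w$chrom]]
    if (is.null(v)) v <- integer(0)
    crs <- find_conserved_regions(w$win_start, w$win_end, v)
    if (nrow(crs) == 0) return(NULL)
    data.frame(gene_id = w$gene_id, chrom = w$chrom, start = crs$start,
               end = crs$end, length_bp = crs$length_bp,
               offset_bp = cr_offset(crs$start, crs$end, w$gene_start,
                                     w$gene_end, w$strand))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length_bp = integer(0), offset_bp = integer(0)))
  }
  do.call(rbind, rows)
}

#' Summarise conserved regions across promoters
#'
#' A CR is *targetable* when strictly longer than `min_targetable_bp`
#' (default 30, i.e. length >= 31). The mean targetable count divides by
#' the number of analysed promoters, including promoters with no CR at all.
#' The size histogram covers all CRs; the offset histogram covers targetable
#' CRs only, in 50-bp bins over `[-window_bp, 0]`.
#'
#' @param crs CR table from [conserved_regions()]
#' @param analyzed_gene_ids ids of every analysed promoter (denominator of
#'   the mean; must contain every gene in `crs`)
#' @param min_targetable_bp targetability threshold, exclusive (default 30)
#' @param window_bp window size used (for the offset histogram range)
#' @param offset_bin_bp offset histogram bin width
#' @return list with `per_gene` (gene_id, n_crs, n_targetable),
#'   `mean_targetable_per_promoter`, `n_promoters`, `total_crs`,
#'   `total_targetable`, `size_hist` (length_bp, count) and `offset_hist`
#'   (bin_start, bin_end, count)
#' @export
summarize_crs <- function(crs, analyzed_gene_ids, min_targetable_bp = 30,
                          window_bp = 1000, offset_bin_bp = 50) {
  .assert(length(analyzed_gene_ids) > 0, "no promoters analysed")
  .assert(all(crs$gene_id %in% analyzed_gene_ids),
          "crs contains genes outside analyzed_gene_ids")
  targetable <- crs$length_bp > min_targetable_bp
  per_gene <- data.frame(gene_id = analyzed_gene_ids)
  cnt <- table(factor(crs$gene_id, levels = analyzed_gene_ids))
  tcnt <- table(factor(crs$gene_id[targetable], levels = analyzed_gene_ids))
  per_gene$n_crs <- as.integer(cnt)
  per_gene$n_targetable <- as.integer(tcnt)
  size_tab <- table(crs$length_bp)
  size_hist <- data.frame(length_bp = as.integer(names(size_tab)),
                          count = as.integer(size_tab))
  breaks <- seq(-window_bp, 0, by = offset_bin_bp)
  off <- crs$offset_bp[targetable]
  oh <- if (length(off) > 0) {
    as.integer(table(cut(off, breaks = breaks, include.lowest = TRUE)))
  } else rep(0L, length(breaks) - 1)
  offset_hist <- data.frame(bin_start = breaks[-length(breaks)],
                            bin_end = breaks[-1], count = as.integer(oh))
  list(per_gene = per_gene,
       mean_targetable_per_promoter = sum(targetable) /
         length(analyzed_gene_ids),
       n_promoters = length(analyzed_gene_ids),
       total_crs = nrow(crs),
       total_targetable = sum(targetable),
       size_hist = size_hist,
       offset_hist = offset_hist)
}

#' Enumerate candidate PTA target sites (20-nt protospacer + NGG PAM)
#'
#' Scans both strands of each promoter window for 20-nt protospacers
#' immediately 5' of an NGG protospacer-adjacent motif. A site is reported
#' when its full protospacer lies within the window (the PAM may extend up
#' to 3 bp past the window edge, sequence permitting). Sites whose
#' protospacer or PAM contains non-ACGT symbols are skipped with a warning.
#' `inside_cr` marks protospacers contained entirely within a single
#' targetable CR; `unique_in_genome` marks protospacers occurring exactly
#' once in the supplied genome (both strands, exact match).
#'
#' @param genome a [Biostrings::DNAStringSet] named by chromosome
#' @param windows window table from [extract_promoter_windows()]
#' @param crs optional CR table from [conserved_regions()] for `inside_cr`
#' @param min_targetable_bp CR targetability threshold (exclusive)
#' @param check_unique compute genome-wide uniqueness (exact match, both
#'   strands); skip with `FALSE` for speed
#' @return data.frame with columns `gene_id`, `protospacer`, `proto_start`,
#'   `proto_end` (genomic, 1-based closed), `pam_position` (genomic
#'   coordinate of the PAM's N), `strand`, `inside_cr`, `unique_in_genome`
#' @export
enumerate_pta_sites <- function(genome, windows, crs = NULL,
                                min_targetable_bp = 30,
                                check_unique = TRUE) {
  .assert(methods::is(genome, "DNAStringSet"), "genome must be a DNAStringSet")
  plen <- 20L
  rows <- list()
  skipped <- 0L
  for (i in which(windows$length_bp > 0)) {
    w <- windows[i, ]
    .assert(w$chrom %in% names(genome),
            "genome does not contain chromosome ", w$chrom)
    chrom_seq <- genome[[w$chrom]]
    # extend by 3 bp of genomic context so PAMs can straddle the window edge
    ext_start <- max(1L, w$win_start - 3L)
    ext_end <- min(length(chrom_seq), w$win_end + 3L)
    seq <- chrom_seq[ext_start:ext_end]
    sseq <- as.character(seq)
    # plus strand: protospacer [q-20, q-1], PAM N at q, GG at q+1, q+2
    gg <- Biostrings::start(Biostrings::matchPattern("GG", seq))
    for (g in gg) {
      q <- g - 1L                     # PAM N, extended-local coords
      ps <- q - plen; pe <- q - 1L    # protospacer
      gs <- ext_start + ps - 1L; ge <- ext_start + pe - 1L
      if (ps < 1L || gs < w$win_start || ge > w$win_end) next
      proto <- substr(sseq, ps, pe)
      pam <- substr(sseq, q, min(q + 2L, nchar(sseq)))
      if (grepl("[^ACGT]", proto) || grepl("[^ACGT]", pam)) {
        skipped <- skipped + 1L; next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = w$gene_id, protospacer = proto,
        proto_start = gs, proto_end = ge,
        pam_position = ext_start + q - 1L, strand = "+")
    }
    # minus strand: genomic CCN at [c, c+2], protospacer revcomp of
    # genomic [c+3, c+22]
    cc <- Biostrings::start(Biostrings::matchPattern("CC", seq))
    for (cpos in cc) {
      ps <- cpos + 3L; pe <- cpos + 22L
      gs <- ext_start + ps - 1L; ge <- ext_start + pe - 1L
      if (pe > nchar(sseq) || gs < w$win_start || ge > w$win_end) next
      proto_fwd <- substr(sseq, ps, pe)
      pam_fwd <- substr(sseq, cpos, cpos + 2L)
      if (grepl("[^ACGT]", proto_fwd) || grepl("[^ACGT]", pam_fwd)) {
        skipped <- skipped + 1L; next
      }
      proto <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(proto_fwd)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = w$gene_id, protospacer = proto,
        proto_start = gs, proto_end = ge,
        pam_position = ext_start + cpos + 2L - 1L, strand = "-")
    }
  }
  if (skipped > 0) {
    warning(skipped, " candidate site(s) overlapping non-ACGT symbols ",
            "were skipped")
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), protospacer = character(0),
                      proto_start = integer(0), proto_end = integer(0),
                      pam_position = integer(0), strand = character(0),
                      inside_cr = logical(0), unique_in_genome = logical(0)))
  }
  sites <- do.call(rbind, rows)
  sites$inside_cr <- FALSE
  if (!is.null(crs) && nrow(crs) > 0) {
    tg <- crs[crs$length_bp > min_targetable_bp, ]
    for (j in seq_len(nrow(sites))) {
      g <- tg[tg$gene_id == sites$gene_id[j], ]
      sites$inside_cr[j] <- any(g$start <= sites$proto_start[j] &
                                g$end >= sites$proto_end[j])
    }
  }
  sites$unique_in_genome <- NA
  if (check_unique) {
    uniq <- character(0)
    for (p in unique(sites$protospacer)) {
      pat <- Biostrings::DNAString(p)
      nfwd <- sum(Biostrings::vcountPattern(pat, genome))
      nrev <- sum(Biostrings::vcountPattern(
        Biostrings::reverseComplement(pat), genome))
      if (nfwd + nrev == 1L) uniq <- c(uniq, p)
    }
    sites$unique_in_genome <- sites$protospacer %in% uniq
  }
  sites
}

#' Read gene annotations from a GFF3 file
#'
#' @param path GFF3 file
#' @param feature_type feature type to keep (default `"gene"`)
#' @param chrom optional chromosome subset
#' @return gene table for [extract_promoter_windows()]
#' @export
read_gene_annotations <- function(path, feature_type = "gene",
                                  chrom = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (!is.null(chrom)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% chrom]
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else names(gr)
  .assert(!is.null(ids) && !any(is.na(ids)),
          "GFF3 features need ID attributes")
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Read single-nucleotide variant positions from a VCF file
#'
#' Keeps biallelic and multi-allelic single-nucleotide records (a
#' multi-allelic SNV counts as one disqualified position); indels and other
#' non-SNV records are excluded and their count reported in a message.
#'
#' @param path VCF 4.x file (plain text or gzipped)
#' @param chrom optional chromosome subset
#' @return named list of sorted unique positions per chromosome
#' @export
read_variant_positions <- function(path, chrom = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  chroms <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  is_snv <- nchar(ref) == 1 &
    vapply(strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE),
           function(a) length(a) > 0 && all(nchar(a) == 1 & a %in%
                                            c("A", "C", "G", "T")),
           TRUE)
  if (any(!is_snv)) {
    message(sum(!is_snv), " non-SNV record(s) (indels or symbolic alleles) ",
            "excluded")
  }
  chroms <- chroms[is_snv]; pos <- pos[is_snv]
  if (!is.null(chrom)) {
    keep <- chroms %in% chrom
    chroms <- chroms[keep]; pos <- pos[keep]
  }
  lapply(split(pos, chroms), function(p) sort(unique(p)))
}

#' Write conserved regions as BED (0-based half-open)
#'
#' @param crs CR table from [conserved_regions()]
#' @param path output BED file
#' @return `path`, invisibly
#' @export
write_crs_bed <- function(crs, path) {
  bed <- data.frame(chrom = crs$chrom, start = crs$start - 1L,
                    end = crs$end,
                    name = paste0(crs$gene_id, "_CR"),
                    score = crs$length_bp,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
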