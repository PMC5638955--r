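#' Specification for a synthetic genome with genes and SNPs
#'
#' A single random chromosome with `n_genes` non-overlapping genes placed
#' uniformly on random strands, and single-nucleotide variants placed
#' independently at every base with probability `snp_prob_per_bp`
#' (a Bernoulli, approximately Poisson, point process — the model under
#' which the expected number of maximal SNP-free runs of length at least
#' \eqn{L} in a window of \eqn{W} bases has the closed form
#' \eqn{(1-p)^L (1 + (W-L)p)}).
#'
#' @param chrom_length_bp chromosome length
#' @param n_genes number of genes
#' @param min_gene_len_bp,max_gene_len_bp gene length range
#' @param snp_prob_per_bp per-base SNP probability in \[0, 1\]
#' @param chrom_name chromosome name (default `"chr1"`)
#' @param rng_seed integer seed
#' @return object of class `genome_spec`
#' @export
genome_spec <- function(chrom_length_bp, n_genes, min_gene_len_bp = 500,
                        max_gene_len_bp = 2000, snp_prob_per_bp = 0.02,
                        chrom_name = "chr1", rng_seed = 1L) {
  .assert(chrom_length_bp >= 1, "chromosome length must be positive")
  .assert(n_genes >= 0, "n_genes must be >= 0")
  .assert(min_gene_len_bp >= 1 && max_gene_len_bp >= min_gene_len_bp,
          "invalid gene length range")
  .assert(snp_prob_per_bp >= 0 && snp_prob_per_bp <= 1,
          "snp_prob_per_bp must be in [0, 1]")
  structure(list(chrom_length_bp = as.integer(chrom_length_bp),
                 n_genes = as.integer(n_genes),
                 min_gene_len_bp = as.integer(min_gene_len_bp),
                 max_gene_len_bp = as.integer(max_gene_len_bp),
                 snp_prob_per_bp = snp_prob_per_bp,
                 chrom_name = chrom_name,
                 rng_seed = as.integer(rng_seed)),
            class = "genome_spec")
}

#' Simulate a genome, gene annotation and SNP set with ground truth
#'
#' Places genes uniformly without overlap (bounded retries; placement
#' failure is an error), assigns random strands, draws a uniform-random
#' ACGT sequence, and makes every base a SNP independently with the
#' specified probability (ALT drawn uniformly from the three non-reference
#' bases). The ground truth contains the promoter windows and their
#' conserved regions computed by an independent per-base brute-force scan.
#'
#' @param spec a [genome_spec()]
#' @param window_bp promoter window size used for the ground truth
#' @return list with `genome` (DNAStringSet), `genes` (annotation table),
#'   `variants` (named list of sorted positions), `variant_table`
#'   (`pos`, `ref`, `alt`), `truth` (list: `windows`, `crs` via brute
#'   force), and `spec`
#' @export
simulate_promoters <- function(spec, window_bp = 1000) {
  .assert(inherits(spec, "genome_spec"), "spec must be a genome_spec")
  L <- spec$chrom_length_bp
  out <- withr::with_seed(spec$rng_seed, {
    # gene placement with bounded retries
    genes <- data.frame(start = integer(0), end = integer(0))
    tries <- 0L
    max_tries <- max(1000L, 200L * spec$n_genes)
    while (nrow(genes) < spec$n_genes) {
      tries <- tries + 1L
      if (tries > max_tries) {
        .fail("gene placement failed after ", max_tries,
              " attempts; chromosome too crowded")
      }
      glen <- sample(spec$min_gene_len_bp:spec$max_gene_len_bp, 1)
      if (glen > L) next
      s <- sample.int(L - glen + 1, 1)
      e <- s + glen - 1
      if (nrow(genes) == 0 || all(e < genes$start | s > genes$end)) {
        genes <- rbind(genes, data.frame(start = s, end = e))
      }
    }
    genes <- genes[order(genes$start), , drop = FALSE]
    n <- nrow(genes)
    genes$gene_id <- sprintf("gene%04d", seq_len(n))
    genes$chrom <- spec$chrom_name
    genes$strand <- if (n > 0) sample(c("+", "-"), n, replace = TRUE)
                    else character(0)
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    snp_pos <- which(stats::runif(L) < spec$snp_prob_per_bp)
    alt <- vapply(snp_pos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"), seq_chars[p]), 1)
    }, character(1))
    list(genes = genes, seq_chars = seq_chars, snp_pos = snp_pos, alt = alt)
  })
  genes <- out$genes[, c("gene_id", "chrom", "start", "end", "strand")]
  genome <- Biostrings::DNAStringSet(paste(out$seq_chars, collapse = ""))
  names(genome) <- spec$chrom_name
  chrom_lengths <- stats::setNames(L, spec$chrom_name)
  windows <- if (nrow(genes) > 0) {
    suppressWarnings(extract_promoter_windows(genes, chrom_lengths,
                                              window_bp))
  } else NULL
  truth_crs <- if (!is.null(windows)) {
    rows <- lapply(which(windows$length_bp > 0), function(i) {
      w <- windows[i, ]
      crs <- .crs_bruteforce(w$win_start, w$win_end, out$snp_pos)
      if (nrow(crs) == 0) return(NULL)
      cbind(gene_id = w$gene_id, crs)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) > 0) do.call(rbind, rows)
    else data.frame(gene_id = character(0), start = integer(0),
                    end = integer(0), length_bp = integer(0))
  } else {
    data.frame(gene_id = character(0), start = integer(0),
               end = integer(0), length_bp = integer(0))
  }
  list(genome = genome,
       genes = genes,
       variants = stats::setNames(list(out$snp_pos), spec$chrom_name),
       variant_table = data.frame(pos = out$snp_pos,
                                  ref = out$seq_chars[out$snp_pos],
                                  alt = out$alt),
       truth = list(windows = windows, crs = truth_crs),
       spec = spec)
}

#' Write a simulated genome as FASTA, GFF3 and VCF
#'
#' @param sim result of [simulate_promoters()]
#' @param dir output directory (created if needed); writes `genome.fa`,
#'   `genes.gff3`, `variants.vcf`
#' @return named vector of the three file paths, invisibly
#' @export
write_genome_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  vcf <- file.path(dir, "variants.vcf")
  Biostrings::writeXStringSet(sim$genome, fa)
  if (nrow(sim$genes) > 0) {
    gr <- GenomicRanges::GRanges(
      sim$genes$chrom,
      IRanges::IRanges(sim$genes$start, sim$genes$end),
      strand = sim$genes$strand)
    gr$source <- "ptascreen"
    gr$type <- "gene"
    gr$ID <- sim$genes$gene_id
    rtracklayer::export(gr, gff, format = "gff3")
    # add the sequence-region pragma (window truncation needs the true
    # chromosome length) and drop the volatile date line for determinism
    lines <- readLines(gff)
    lines <- lines[!grepl("^##(date|source-version)", lines)]
    writeLines(c(lines[1],
                 paste("##sequence-region", sim$spec$chrom_name, 1,
                       sim$spec$chrom_length_bp),
                 lines[-1]), gff)
  } else {
    writeLines(c("##gff-version 3",
                 paste("##sequence-region", sim$spec$chrom_name, 1,
                       sim$spec$chrom_length_bp)), gff)
  }
  chrom <- sim$spec$chrom_name
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ",length=",
                  sim$spec$chrom_length_bp, ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(sim$variant_table) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, sim$variant_table$pos,
            sim$variant_table$ref, sim$variant_table$alt)
  } else character(0)
  writeLines(c(hdr, body), vcf)
  invisible(c(fasta = fa, gff3 = gff, vcf = vcf))
}
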