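#' Configuration of the synthetic-data generator
#'
#' Collects the knobs of the generator: gene/intron geometry, expression
#' distribution, the per-species drift-barrier model driving true AS rates,
#' read simulation (depth, read length, retention), deliberately injected
#' filter violations, and SNP densities. Defaults emulate a compact
#' metazoan-like gene set: ~5 introns per gene (metazoan clade means range
#' from ~2.8 to ~8.4), log-normal expression, 98% GT-AG introns and the
#' low-Ne drift-barrier model for true AS rates.
#'
#' Minor-variant boundary offsets are drawn uniformly on
#' `minor_offset_range` (default 4-33 bp) for error variants — a range
#' whose frame-preserving fraction is exactly 1/3 both overall and within
#' the 30-bp evaluation window, while keeping the planted minor splice
#' signal clear of the major one — and as multiples of 3 within 30 bp for
#' functional variants.
#'
#' @param n_genes Number of genes.
#' @param introns_per_gene Integer range `c(min, max)` of introns per gene.
#' @param exon_len,intron_len Integer ranges of exon / intron lengths (bp).
#' @param expression_meanlog,expression_sdlog Log-normal expression
#'   parameters (natural log).
#' @param model A [model_params()] object for true per-intron AS rates.
#' @param expression_error_coupling Exponent linking the splicing-error
#'   rate to relative expression (negative = highly expressed genes are
#'   spliced more accurately; 0 disables the coupling).
#' @param read_depth Mean junction reads per intron for a gene at the
#'   median expression level.
#' @param read_len Read length in bp (default 100).
#' @param retention_rate Retention (unspliced) reads per intron boundary,
#'   as a fraction of the junction depth.
#' @param signal_probs Named probabilities of the three splice signals.
#' @param minor_offset_range Uniform range of error-variant offsets (bp).
#' @param frac_short_anchor,frac_high_mismatch,frac_multi Fractions of
#'   extra junction reads injected with anchors below the quantification
#'   minimum, with mismatch ratio above 0.02, or flagged multi-mapping.
#' @param snp_background Background SNP density per base.
#' @param snp_factor_major,snp_factor_minor_abundant,snp_factor_minor_rare
#'   Multiplicative SNP-density reduction factors at major splice
#'   dinucleotides and at minor splice dinucleotides of abundant / rare
#'   variants.
#' @param intergenic Intergenic spacer length (bp).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 30L,
                             introns_per_gene = c(3L, 7L),
                             exon_len = c(120L, 250L),
                             intron_len = c(150L, 500L),
                             expression_meanlog = log(50),
                             expression_sdlog = 1,
                             model = model_params(),
                             expression_error_coupling = 0,
                             read_depth = 50,
                             read_len = 100L,
                             retention_rate = 0.05,
                             signal_probs = c("GT-AG" = 0.98,
                                              "GC-AG" = 0.015,
                                              "AT-AC" = 0.005),
                             minor_offset_range = c(4L, 33L),
                             frac_short_anchor = 0,
                             frac_high_mismatch = 0,
                             frac_multi = 0,
                             snp_background = 0.005,
                             snp_factor_major = 0.2,
                             snp_factor_minor_abundant = 0.5,
                             snp_factor_minor_rare = 1,
                             intergenic = 400L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1L, cfg$intron_len[1L] >= 40L,
            cfg$exon_len[1L] >= 80L, cfg$read_len >= 40L,
            cfg$minor_offset_range[1L] >= 2L,
            abs(sum(cfg$signal_probs) - 1) < 1e-8,
            cfg$snp_background >= 0)
  class(cfg) <- "synthetic_config"
  cfg
}

# uniform integer draws from an inclusive range (safe when min == max)
sample_range <- function(range, n) {
  vals <- seq.int(range[1L], range[2L])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# stamp strings into a character-vector genome at 1-based positions
# (single vectorized assignment; planted motifs never overlap by design)
.plant_all <- function(seqchars, pos, what) {
  nc <- nchar(what)
  idx <- sequence(nc, from = pos)
  seqchars[idx] <- unlist(strsplit(what, ""), use.names = FALSE)
  seqchars
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]),
                                     collapse = ""), ""))
}

#' Generate a synthetic genome, annotation and truth table
#'
#' Builds one chromosome of spaced genes, each with alternating exons and
#' introns, planted splice signals (majority GT-AG), start/stop codons
#' bracketing the coding span, and — for every intron — one minor splice
#' variant whose boundary offset, shared side and exonic/intronic location
#' are recorded in the truth table together with the intron's true AS rate
#' (drawn from the configured drift-barrier model) and the gene's
#' expression level. Fully deterministic given `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A `synthetic_data` list: `genome` (DNAStringSet), `features`
#'   (GTF-style feature table), `annotation` (a `gene_annotation`), `truth`
#'   (list with `introns` and `genes` data.frames), `config`, `seed`.
#' @export
generate_annotation <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"), !missing(seed))
  set.seed(seed)
  cfg <- config
  genes <- list()
  introns <- list()
  pos <- 1L
  chrom <- "chr1"
  features <- list()
  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("g%03d", g)
    tx_id <- paste0("tx_", gene_id)
    strand <- sample(c("+", "-"), 1L)
    ni <- sample_range(cfg$introns_per_gene, 1L)
    ex_len <- sample_range(cfg$exon_len, ni + 1L)
    in_len <- sample_range(cfg$intron_len, ni)
    gene_start <- pos + cfg$intergenic
    cursor <- gene_start
    ex_start <- integer(ni + 1L)
    ex_end <- integer(ni + 1L)
    in_start <- integer(ni)
    in_end <- integer(ni)
    for (i in seq_len(ni + 1L)) {
      ex_start[i] <- cursor
      ex_end[i] <- cursor + ex_len[i] - 1L
      cursor <- ex_end[i] + 1L
      if (i <= ni) {
        in_start[i] <- cursor
        in_end[i] <- cursor + in_len[i] - 1L
        cursor <- in_end[i] + 1L
      }
    }
    gene_end <- ex_end[ni + 1L]
    pos <- gene_end + 1L
    signal <- sample(names(cfg$signal_probs), ni, replace = TRUE,
                     prob = cfg$signal_probs)
    genes[[g]] <- data.frame(
      gene_id = gene_id, chrom = chrom, strand = strand,
      gene_start = gene_start, gene_end = gene_end,
      stringsAsFactors = FALSE)
    if (ni) {
      introns[[g]] <- data.frame(
        gene_id = gene_id, chrom = chrom, intron_start = in_start,
        intron_end = in_end, strand = strand, signal = signal,
        stringsAsFactors = FALSE)
    }
    features[[g]] <- data.frame(
      chrom = chrom,
      start = c(ex_start,
                if (strand == "+") gene_start else gene_end - 2L,
                if (strand == "+") gene_end - 2L else gene_start),
      end = c(ex_end,
              if (strand == "+") gene_start + 2L else gene_end,
              if (strand == "+") gene_end else gene_start + 2L),
      strand = strand,
      type = c(rep("exon", ni + 1L), "start_codon", "stop_codon"),
      gene_id = gene_id, transcript_id = tx_id,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  introns <- do.call(rbind, introns)
  features <- do.call(rbind, features)
  L <- pos + cfg$intergenic

  # gene expression and true AS rates (drift-barrier model + optional
  # expression coupling of the error rate)
  genes$expression <- rlnorm(nrow(genes), cfg$expression_meanlog,
                             cfg$expression_sdlog)
  m <- cfg$model
  n_in <- nrow(introns)
  func <- runif(n_in) < m$functional_fraction
  as_rate <- numeric(n_in)
  if (any(func)) {
    x <- rnorm(sum(func), m$functional_mean, m$functional_sd)
    x <- pmin(pmax(x, 0.01), 0.95)
    as_rate[func] <- x
  }
  err <- rgamma(sum(!func), shape = m$error_shape,
                scale = m$error_mean / m$error_shape)
  if (cfg$expression_error_coupling != 0) {
    rel <- genes$expression[match(introns$gene_id[!func], genes$gene_id)] /
      exp(cfg$expression_meanlog)
    err <- err * rel^cfg$expression_error_coupling
  }
  as_rate[!func] <- pmin(err, 0.9)
  introns$as_rate <- as_rate
  introns$is_functional <- func

  # minor-variant geometry: shared side, exonic/intronic location, offset
  introns$shared_side <- sample(c("donor", "acceptor"), n_in,
                                replace = TRUE)
  introns$minor_location <- sample(c("exonic", "intronic"), n_in,
                                   replace = TRUE)
  off <- integer(n_in)
  off[func] <- 3L * sample(10L, sum(func), replace = TRUE)
  off[!func] <- sample(seq(cfg$minor_offset_range[1L],
                           cfg$minor_offset_range[2L]),
                       sum(!func), replace = TRUE)
  introns$minor_offset <- off
  # the shared boundary in genomic terms: donor = start on "+", end on "-"
  shared_start <- (introns$shared_side == "donor") ==
    (introns$strand == "+")
  delta <- ifelse(introns$minor_location == "intronic", -off, off)
  introns$minor_start <- ifelse(shared_start, introns$intron_start,
                                introns$intron_start - delta)
  introns$minor_end <- ifelse(shared_start, introns$intron_end + delta,
                              introns$intron_end)
  introns$frame_preserving <- off %% 3L == 0L

  # sequence: random background, then planted signals and codons
  seqchars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  st <- .signal_table
  srow <- match(paste(introns$signal, introns$strand),
                paste(st$signal, st$strand))
  # non-shared minor boundary gets the same signal class as its major intron
  plant_pos <- c(introns$intron_start, introns$intron_end - 1L,
                 ifelse(shared_start, introns$minor_end - 1L,
                        introns$minor_start),
                 ifelse(genes$strand == "+", genes$gene_start,
                        genes$gene_end - 2L),
                 ifelse(genes$strand == "+", genes$gene_end - 2L,
                        genes$gene_start))
  plant_txt <- c(st$din5[srow], st$din3[srow],
                 ifelse(shared_start, st$din3[srow], st$din5[srow]),
                 ifelse(genes$strand == "+", "ATG", "CAT"),
                 ifelse(genes$strand == "+", "TAA", "TTA"))
  seqchars <- .plant_all(seqchars, plant_pos, plant_txt)
  genome <- Biostrings::DNAStringSet(
    setNames(paste(seqchars, collapse = ""), chrom))

  ann <- list(
    exons = features[features$type == "exon",
                     c("gene_id", "transcript_id", "chrom", "start", "end",
                       "strand")],
    start_codons = features[features$type == "start_codon",
                            c("gene_id", "chrom", "start", "end",
                              "strand")],
    stop_codons = features[features$type == "stop_codon",
                           c("gene_id", "chrom", "start", "end",
                             "strand")])
  rownames(ann$exons) <- rownames(ann$start_codons) <-
    rownames(ann$stop_codons) <- NULL
  ann$genes <- unique(ann$exons[, c("gene_id", "chrom", "strand")])
  rownames(ann$genes) <- NULL
  ann$introns <- derive_annotated_introns(ann$exons)
  class(ann) <- "gene_annotation"

  rownames(introns) <- NULL
  out <- list(genome = genome, features = features, annotation = ann,
              truth = list(introns = introns, genes = genes),
              config = cfg, seed = seed)
  class(out) <- "synthetic_data"
  out
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat("synthetic_data:", nrow(x$truth$genes), "genes,",
      nrow(x$truth$introns), "introns on",
      length(x$genome), "chromosome(s) of total",
      sum(Biostrings::width(x$genome)), "bp\n")
  invisible(x)
}

#' Simulate spliced reads from a synthetic truth table
#'
#' Realises the truth table as alignments: for each intron, the number of
#' junction reads is Poisson with mean `depth * expression / median
#' expression`; each junction read excises the minor intron with
#' probability equal to the true AS rate, the major intron otherwise.
#' Anchors are drawn uniformly subject to the detection minimum.
#' Retention (unspliced) reads are generated per boundary at
#' `retention_rate` times the junction depth, covering at least 10 bp on
#' each side. Configured fractions of extra reads violate the anchor,
#' mismatch-ratio or uniqueness filters (for exercising the extraction
#' filters) and are tallied in the output.
#'
#' @param sim A `synthetic_data` object from [generate_annotation()].
#' @param depth Mean junction reads per intron at median expression
#'   (default `sim$config$read_depth`).
#' @param seed Integer seed.
#' @param min_anchor Minimum anchor of clean simulated reads (default 8).
#' @return A list: `alignments` (read table in the [read_sam()] schema),
#'   `expected` (per-intron realised `NM_true`, `Nim_true`), `violations`
#'   (named counts of injected filter-violating reads).
#' @export
simulate_reads <- function(sim, depth = sim$config$read_depth, seed,
                           min_anchor = 8L) {
  stopifnot(inherits(sim, "synthetic_data"), !missing(seed))
  set.seed(seed)
  cfg <- sim$config
  tr <- sim$truth$introns
  genes <- sim$truth$genes
  R <- cfg$read_len
  expr <- genes$expression[match(tr$gene_id, genes$gene_id)]
  lambda <- depth * expr / exp(cfg$expression_meanlog)
  n_jx <- rpois(nrow(tr), lambda)
  n_minor <- rbinom(nrow(tr), n_jx, tr$as_rate)
  n_major <- n_jx - n_minor

  mk_junction <- function(s, e, n, anchor_min) {
    if (!n) return(NULL)
    a <- sample(seq(anchor_min, R - anchor_min), n, replace = TRUE)
    data.frame(pos = s - a,
               cigar = sprintf("%dM%dN%dM", a, e - s + 1L, R - a),
               stringsAsFactors = FALSE)
  }
  blocks <- vector("list", 4L * nrow(tr))
  bi <- 0L
  add <- function(d) {
    if (!is.null(d) && nrow(d)) {
      bi <<- bi + 1L
      blocks[[bi]] <<- d
    }
  }
  for (i in seq_len(nrow(tr))) {
    add(mk_junction(tr$intron_start[i], tr$intron_end[i], n_major[i],
                    min_anchor))
    add(mk_junction(tr$minor_start[i], tr$minor_end[i], n_minor[i],
                    min_anchor))
    for (b in c(tr$intron_start[i], tr$intron_end[i] + 1L)) {
      nr <- rpois(1L, cfg$retention_rate * lambda[i])
      if (nr) {
        p <- sample(seq(b - R + 10L, b - 10L), nr, replace = TRUE)
        add(data.frame(pos = p, cigar = paste0(R, "M"),
                       stringsAsFactors = FALSE))
      }
    }
  }
  aln <- if (bi) do.call(rbind, blocks[seq_len(bi)]) else
    data.frame(pos = integer(), cigar = character(),
               stringsAsFactors = FALSE)
  aln$mismatch_count <- integer(nrow(aln))
  aln$is_unique <- rep(TRUE, nrow(aln))

  # injected violations: extra junction reads failing one filter each
  n_clean <- sum(n_jx)
  viol <- c(short_anchor = rpois(1L, cfg$frac_short_anchor * n_clean),
            high_mismatch = rpois(1L, cfg$frac_high_mismatch * n_clean),
            multi_mapping = rpois(1L, cfg$frac_multi * n_clean))
  if (sum(viol)) {
    idx <- sample(nrow(tr), sum(viol), replace = TRUE)
    vtype <- rep(names(viol), viol)
    a <- ifelse(vtype == "short_anchor", 3L,
                sample(seq(min_anchor, R - min_anchor), sum(viol),
                       replace = TRUE))
    vd <- data.frame(
      pos = tr$intron_start[idx] - a,
      cigar = sprintf("%dM%dN%dM", a,
                      tr$intron_end[idx] - tr$intron_start[idx] + 1L,
                      R - a),
      mismatch_count = ifelse(vtype == "high_mismatch",
                              as.integer(ceiling(0.03 * R)), 0L),
      is_unique = vtype != "multi_mapping",
      stringsAsFactors = FALSE)
    aln <- rbind(aln, vd)
  }
  aln$read_id <- sprintf("r%07d", seq_len(nrow(aln)))
  aln$chrom <- rep(tr$chrom[1L], nrow(aln))
  aln <- aln[, c("read_id", "chrom", "pos", "cigar", "mismatch_count",
                 "is_unique")]
  expected <- data.frame(
    chrom = tr$chrom, intron_start = tr$intron_start,
    intron_end = tr$intron_end, NM_true = n_major, Nim_true = n_minor,
    stringsAsFactors = FALSE)
  list(alignments = aln, expected = expected, violations = viol)
}

#' Simulate SNPs over a synthetic genome
#'
#' Places SNPs independently per base at the background density, multiplied
#' by reduction factors at major splice-site dinucleotides and at the
#' non-shared minor splice dinucleotides of abundant (true AS > 5%) and
#' rare variants — emulating purifying selection on constrained splice
#' sites.
#'
#' @param sim A `synthetic_data` object.
#' @param seed Integer seed.
#' @param background,factor_major,factor_minor_abundant,factor_minor_rare
#'   Densities and reduction factors (defaults from `sim$config`).
#' @return A data.frame of SNPs: `chrom`, `pos`, `ref`, `alt`.
#' @export
simulate_snps <- function(sim, seed,
                          background = sim$config$snp_background,
                          factor_major = sim$config$snp_factor_major,
                          factor_minor_abundant =
                            sim$config$snp_factor_minor_abundant,
                          factor_minor_rare =
                            sim$config$snp_factor_minor_rare) {
  stopifnot(inherits(sim, "synthetic_data"), !missing(seed))
  set.seed(seed)
  tr <- sim$truth$introns
  chrom <- names(sim$genome)[1L]
  L <- Biostrings::width(sim$genome)[1L]
  prob <- rep(background, L)
  major_pos <- c(tr$intron_start, tr$intron_start + 1L,
                 tr$intron_end - 1L, tr$intron_end)
  prob[major_pos] <- background * factor_major
  shared_start <- tr$minor_start == tr$intron_start
  minor_p1 <- ifelse(shared_start, tr$minor_end - 1L, tr$minor_start)
  minor_pos <- c(minor_p1, minor_p1 + 1L)
  minor_factor <- rep(ifelse(tr$as_rate > 0.05, factor_minor_abundant,
                             factor_minor_rare), 2L)
  prob[minor_pos] <- background * minor_factor
  hit <- which(runif(L) < prob)
  if (!length(hit)) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  chseq <- as.character(sim$genome[[1L]])
  ref <- substring(chseq, hit, hit)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1L), "", USE.NAMES = FALSE)
  data.frame(chrom = chrom, pos = hit, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Simulate a clade with Brownian life-history traits
#'
#' Generates a pure-birth tree, evolves log-longevity along it by Brownian
#' motion, couples each species' mean splicing-error rate to longevity
#' (`log error_mean = a + b * log longevity`, the drift-barrier
#' expectation: longer-lived species have smaller Ne, hence a higher error
#' rate for `b > 0`), and summarises each species' genome-wide AS by
#' simulating `n_introns` introns from its drift-barrier model.
#'
#' @param n_taxa Number of species (>= 3).
#' @param seed Integer seed.
#' @param birth Speciation rate of the pure-birth tree.
#' @param root_longevity Longevity at the root (years).
#' @param bm_sigma Brownian standard deviation of log-longevity per unit
#'   branch length.
#' @param trait_coupling Slope `b` linking log error rate to
#'   log-longevity.
#' @param base_error Error-rate mean of a species at root longevity.
#' @param n_introns Introns simulated per species for the AS summary.
#' @param model Template [model_params()] for the non-error parameters.
#' @return A list: `tree` (ape phylo), `traits` (data.frame `species`,
#'   `longevity`, `log_longevity`, `error_mean`, `mean_as`).
#' @export
simulate_clade <- function(n_taxa = 40L, seed, birth = 1,
                           root_longevity = 5, bm_sigma = 1,
                           trait_coupling = 0.5, base_error = 0.004,
                           n_introns = 20000L, model = model_params()) {
  stopifnot(n_taxa >= 3L, !missing(seed))
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth, death = 0)
  z <- ape::rTraitCont(tree, model = "BM", sigma = bm_sigma,
                       root.value = log(root_longevity))
  err <- base_error * exp(trait_coupling * (z - log(root_longevity)))
  err <- pmin(pmax(err, 1e-4), 0.05)
  mean_as <- vapply(err, function(e) {
    p <- model_params(n_introns = n_introns,
                      functional_fraction = model$functional_fraction,
                      functional_mean = model$functional_mean,
                      functional_sd = model$functional_sd,
                      error_shape = model$error_shape, error_mean = e,
                      frameshift_fraction_errors =
                        model$frameshift_fraction_errors,
                      as_threshold = model$as_threshold)
    mean(simulate_species(p)$as_rate)
  }, numeric(1L))
  traits <- data.frame(species = tree$tip.label,
                       longevity = exp(unname(z)),
                       log_longevity = unname(z),
                       error_mean = unname(err),
                       mean_as = mean_as,
                       stringsAsFactors = FALSE)
  list(tree = tree, traits = traits)
}

#' Write all files of a synthetic dataset
#'
#' Writes genome FASTA, annotation GTF, truth tables (TSV) and, when
#' provided, alignments (SAM), SNPs (VCF), tree (Newick) and traits (TSV)
#' into a directory.
#'
#' @param sim A `synthetic_data` object.
#' @param dir Output directory (created if absent).
#' @param reads Optional result of [simulate_reads()].
#' @param snps Optional result of [simulate_snps()].
#' @param clade Optional result of [simulate_clade()].
#' @return The directory path, invisibly.
#' @export
write_synthetic_data <- function(sim, dir, reads = NULL, snps = NULL,
                                 clade = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sl <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$features, file.path(dir, "annotation.gtf"))
  write.table(sim$truth$introns, file.path(dir, "truth_introns.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reads))
    write_sam(reads$alignments, sl, file.path(dir, "reads.sam"))
  if (!is.null(snps))
    write_vcf(snps, sl, file.path(dir, "snps.vcf"))
  if (!is.null(clade)) {
    ape::write.tree(clade$tree, file.path(dir, "tree.nwk"))
    write.table(clade$traits, file.path(dir, "traits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
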