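# Independent brute-force oracles and tiny fixture builders.
# The oracles deliberately use a different algorithm (per-read character
# walk) from the package's vectorized implementation.

aln_row <- function(read_id = "r1", chrom = "chr1", pos = 1L, cigar = "100M",
                    mismatch_count = 0L, is_unique = TRUE) {
  data.frame(read_id = read_id, chrom = chrom, pos = as.integer(pos),
             cigar = cigar, mismatch_count = as.integer(mismatch_count),
             is_unique = is_unique, stringsAsFactors = FALSE)
}

toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# naive re-scan of all reads' N ops, walking the CIGAR token by token
naive_extract_junctions <- function(aln, min_anchor = 8L,
                                    max_intron_len = 2000000L,
                                    max_mm = 0.02) {
  rows <- list()
  for (i in seq_len(nrow(aln))) {
    if (!aln$is_unique[i]) next
    toks <- regmatches(aln$cigar[i],
                       gregexpr("[0-9]+[A-Z]", aln$cigar[i]))[[1L]]
    if (!length(toks) ||
        nchar(paste(toks, collapse = "")) != nchar(aln$cigar[i])) next
    lens <- as.integer(sub("[A-Z]$", "", toks))
    ops <- sub("^[0-9]+", "", toks)
    if (any(!ops %in% c("M", "I", "D", "N", "S")) || any(lens <= 0L)) next
    mtot <- sum(lens[ops == "M"])
    if (mtot == 0L || aln$mismatch_count[i] / mtot > max_mm) next
    ref <- aln$pos[i]
    m_since <- 0L
    pending <- NULL
    flush <- function(p, right) {
      p$right_anchor <- right
      rows[[length(rows) + 1L]] <<- p
    }
    for (j in seq_along(ops)) {
      if (ops[j] == "N") {
        if (!is.null(pending)) flush(pending, m_since)
        pending <- data.frame(chrom = aln$chrom[i], intron_start = ref,
                              intron_end = ref + lens[j] - 1L,
                              left_anchor = m_since,
                              read_id = aln$read_id[i],
                              stringsAsFactors = FALSE)
        m_since <- 0L
        ref <- ref + lens[j]
      } else if (ops[j] == "M") {
        m_since <- m_since + lens[j]
        ref <- ref + lens[j]
      } else if (ops[j] == "D") {
        ref <- ref + lens[j]
      }
    }
    if (!is.null(pending)) flush(pending, m_since)
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), left_anchor = integer(),
                      right_anchor = integer(), read_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[out$left_anchor >= min_anchor &
               out$right_anchor >= min_anchor &
               out$intron_end - out$intron_start + 1L <= max_intron_len, ,
             drop = FALSE]
  out <- out[, c("chrom", "intron_start", "intron_end", "left_anchor",
                 "right_anchor", "read_id")]
  rownames(out) <- NULL
  out
}

# brute-force (Ns, Na, Nu) for one focal intron
naive_counts <- function(aln, chrom, s, e, quant_anchor = 5L,
                         overlap = 10L, max_mm = 0.02) {
  ev <- naive_extract_junctions(aln, min_anchor = quant_anchor,
                                max_mm = max_mm)
  ev <- ev[ev$chrom == chrom, , drop = FALSE]
  ns <- sum(ev$intron_start == s & ev$intron_end == e)
  na <- sum(xor(ev$intron_start == s, ev$intron_end == e))
  nu <- 0L
  for (i in seq_len(nrow(aln))) {
    if (!aln$is_unique[i] || aln$chrom[i] != chrom) next
    if (grepl("N", aln$cigar[i], fixed = TRUE)) next
    toks <- regmatches(aln$cigar[i],
                       gregexpr("[0-9]+[A-Z]", aln$cigar[i]))[[1L]]
    lens <- as.integer(sub("[A-Z]$", "", toks))
    ops <- sub("^[0-9]+", "", toks)
    if (any(!ops %in% c("M", "I", "D", "S"))) next
    mtot <- sum(lens[ops == "M"])
    if (mtot == 0L || aln$mismatch_count[i] / mtot > max_mm) next
    lo <- aln$pos[i]
    hi <- lo + sum(lens[ops %in% c("M", "D")]) - 1L
    if (lo <= s - overlap && hi >= s + overlap - 1L) nu <- nu + 1L
    if (lo <= e - overlap + 1L && hi >= e + overlap) nu <- nu + 1L
  }
  c(Ns = ns, Na = na, Nu = nu)
}

# random spliced/unspliced reads exercising all CIGAR op types
random_reads <- function(n, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    spliced <- runif(1) < 0.7
    if (spliced) {
      a <- sample(1:40, 1)
      b <- sample(1:40, 1)
      nlen <- sample(c(30:200, 2000001L), 1)
      mid <- sample(c("", "2I", "3D", "1I2D"), 1)
      cigar <- if (runif(1) < 0.2) {
        c2 <- sample(20:60, 1)
        sprintf("%dM%dN%dM%dN%dM", a, nlen, sample(5:30, 1),
                sample(30:100, 1), c2)
      } else {
        sprintf("%s%dM%s%dN%dM%s", if (runif(1) < 0.2) "4S" else "", a,
                mid, nlen, b, if (runif(1) < 0.2) "3S" else "")
      }
    } else {
      cigar <- sprintf("%dM", sample(30:100, 1))
    }
    aln_row(read_id = sprintf("r%04d", i), pos = sample(1:5000, 1),
            cigar = cigar,
            mismatch_count = sample(0:3, 1),
            is_unique = runif(1) < 0.9)
  })
  do.call(rbind, rows)
}
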