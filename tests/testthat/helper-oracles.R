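# Independent brute-force oracles. These deliberately use naive loops and
# closed-form statistics so that they share no code path with the package.

# naive per-start window counts
oracle_window_counts <- function(protein, width, members) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  if (n < width) return(integer(0))
  vapply(seq_len(n - width + 1L), function(s)
    sum(chars[s:(s + width - 1L)] %in% members), 0L)
}

# greedy selection on a precomputed count vector (max count, ties smallest
# start, exclusion radius on |s1 - s2| <= dist)
oracle_greedy <- function(counts, min_count, dist) {
  starts <- which(counts >= min_count) - 1L
  kept <- integer(0)
  while (length(starts)) {
    cc <- counts[starts + 1L]
    best <- min(starts[cc == max(cc)])
    kept <- c(kept, best)
    starts <- starts[abs(starts - best) > dist]
  }
  sort(kept)
}

# enumeration + greedy selection
oracle_find_tracts <- function(protein, width, members, min_count, dist) {
  oracle_greedy(oracle_window_counts(protein, width, members), min_count,
                dist)
}

oracle_control_starts <- function(protein, width, members, max_count) {
  counts <- oracle_window_counts(protein, width, members)
  which(counts <= max_count) - 1L
}

# region arithmetic straight from the stated rules, in codons:
# post = [last target residue + 1 + 40, sense codons - 20),
# pre  = [20, post start); empty interval => unanalyzable
oracle_regions <- function(n_sense_codons, last_target_res,
                           post_offset = 40L, stop_trim = 20L,
                           start_trim = 20L) {
  post <- c(last_target_res + 1L + post_offset, n_sense_codons - stop_trim)
  pre <- c(start_trim, post[1])
  list(pre_nt = 3L * pre, post_nt = 3L * post,
       analyzable = post[1] < post[2] && pre[1] < pre[2] &&
         post[2] <= n_sense_codons)
}

# brute-force reimplementation of the four exclusion filters
oracle_included <- function(records, wt_totals, protein_lens,
                            min_reads = 25, frac = 0.05, min_stop = 30,
                            n_sd = 2) {
  n <- nrow(records)
  pass3 <- logical(n)
  for (i in seq_len(n)) {
    L <- protein_lens[[records$transcript_id[i]]]
    wt <- wt_totals[[records$transcript_id[i]]]
    ok <- !is.null(wt) && !is.na(wt) && wt >= min_reads
    s <- records$start_res[i]; w <- records$width[i]
    ok <- ok && !(s < frac * L || (s + w) > L - frac * L)
    ok <- ok && (L - 1 - records$last_target_res[i]) >= min_stop
    ok <- ok && isTRUE(records$analyzable[i]) && !is.na(records$ratio[i])
    pass3[i] <- ok
  }
  is_ctrl <- records$window_class == "control"
  ctrl_r <- records$ratio[pass3 & is_ctrl]
  if (length(ctrl_r) >= 2 && is.finite(sd(ctrl_r))) {
    cut <- mean(ctrl_r) + n_sd * sd(ctrl_r)
    pass3 & !is.na(records$ratio) & records$ratio <= cut
  } else pass3
}

# pooled-variance two-sided two-sample t-test from closed form
oracle_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# one-way ANOVA + Tukey HSD from closed form (groups: factor levels order)
oracle_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  m <- mean(values)
  ssb <- sum(ni * (mi - m)^2)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df2 <- N - k
  msw <- ssw / df2
  F <- (ssb / (k - 1)) / msw
  p <- pf(F, k - 1, df2, lower.tail = FALSE)
  lv <- levels(groups)
  pairs <- utils::combn(seq_len(k), 2)
  tuk <- data.frame(
    comparison = apply(pairs, 2, function(ij) paste(lv[ij[2]], lv[ij[1]],
                                                    sep = "-")),
    diff = apply(pairs, 2, function(ij) mi[ij[2]] - mi[ij[1]]),
    se = apply(pairs, 2, function(ij)
      sqrt(msw / 2 * (1 / ni[ij[1]] + 1 / ni[ij[2]]))),
    row.names = NULL)
  tuk$p_adj <- ptukey(abs(tuk$diff) / tuk$se, k, df2, lower.tail = FALSE)
  q <- qtukey(0.95, k, df2)
  tuk$lwr <- tuk$diff - q * tuk$se
  tuk$upr <- tuk$diff + q * tuk$se
  list(F = F, p = p, tukey = tuk)
}

# two-sample Kolmogorov-Smirnov distance
ks_distance <- function(x, y) {
  as.numeric(suppressWarnings(stats::ks.test(x, y)$statistic))
}

# random protein with given residue weights
random_protein <- function(n, weights = NULL) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE, prob = weights), collapse = "")
}

# tally a footprint GRanges into per-nt counts via P-site assignment
tally_gr <- function(gr, n_nt, offset = 15L) {
  pos <- GenomicRanges::start(gr) - 1L + offset
  tabulate(pos + 1L, nbins = n_nt)
}

# uniform coverage fixture on an L-codon (sense) transcript
uniform_track <- function(id, n_sense, per_nt = 2L, library_total = NULL) {
  counts <- rep(per_nt, 3L * (n_sense + 1L))
  coverage_track(id, counts,
                 library_total = if (is.null(library_total)) sum(counts)
                                 else library_total)
}
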