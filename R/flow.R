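#' Read a flow-cytometry event table
#'
#' TSV with one row per event and columns `sample`, `replicate`, `gfp`,
#' `rfp`, `ssc`. All channels must be positive.
#'
#' @param path TSV path.
#' @param min_events Minimum events per (sample, replicate) for summary
#'   statistics; fewer is an error.
#' @return A `data.table` of events.
#' @export
read_flow_tsv <- function(path, min_events = 1000L) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("sample", "replicate", "gfp", "rfp", "ssc")
  if (!all(need %in% names(dt)))
    stop("flow table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(dt$gfp <= 0 | dt$rfp <= 0 | dt$ssc <= 0))
    stop("all flow channels must be positive", call. = FALSE)
  cnt <- dt[, list(n = .N), by = c("sample", "replicate")]
  low <- cnt[cnt$n < min_events, ]
  if (nrow(low))
    stop("sample(s) with fewer than ", min_events, " events: ",
         paste(unique(low$sample), collapse = ", "), call. = FALSE)
  dt
}

#' Side-scatter-normalized, blank-referenced flow summaries
#'
#' Every event's fluorescence channels are divided by its side scatter;
#' per-(sample, replicate) means of those per-event ratios are then divided
#' by the corresponding mean of a blank control (a strain carrying no
#' reporter), pooled over the blank's replicates.
#'
#' @param events Event `data.table` (see [read_flow_tsv()]).
#' @param blank Event `data.table` for the blank control.
#' @param geometric Use geometric instead of arithmetic means.
#' @return A `data.table` with one row per (sample, replicate):
#'   `gfp_norm`, `rfp_norm`.
#' @export
normalize_flow <- function(events, blank, geometric = FALSE) {
  if (is.null(blank) || !nrow(blank))
    stop("blank control sample is required", call. = FALSE)
  avg <- if (geometric) function(x) exp(mean(log(x))) else mean
  blank_gfp <- avg(blank$gfp / blank$ssc)
  blank_rfp <- avg(blank$rfp / blank$ssc)
  ev <- data.table::as.data.table(events)
  out <- ev[, list(gfp_norm = avg(gfp / ssc) / blank_gfp,
                   rfp_norm = avg(rfp / ssc) / blank_rfp),
            by = c("sample", "replicate")]
  out[]
}

#' RFP/GFP read-through ratio of a stalling vs nonstalling reporter
#'
#' @param stall_summary,nonstall_summary Lists or one-row tables with
#'   `gfp_norm` and `rfp_norm` (replicate means are taken if several rows).
#' @return Percent: `100 * (rfp/gfp)_stall / (rfp/gfp)_nonstall`.
#' @export
readthrough_ratio <- function(stall_summary, nonstall_summary) {
  rg <- function(s) {
    g <- mean(s$gfp_norm); r <- mean(s$rfp_norm)
    if (g <= 0) stop("non-positive GFP summary", call. = FALSE)
    r / g
  }
  100 * rg(stall_summary) / rg(nonstall_summary)
}

#' Group statistics for flow summaries: mean, SEM, ANOVA and Tukey HSD
#'
#' One-way analysis of variance across strains followed by Tukey's honestly
#' significant difference test, on per-replicate summary values.
#'
#' @param summaries `data.frame` with columns `strain`, `replicate` and
#'   `value` (one summary statistic per biological replicate).
#' @return A list: `groups` (strain, n, mean, sem), `anova_F`, `anova_p`,
#'   `tukey` (data.table: comparison, diff, lwr, upr, p_adj). Strains with a
#'   single replicate are dropped from inference with a warning. When all
#'   groups are identical constants, `anova_F = 0`, `anova_p = 1` and every
#'   pairwise p is 1.
#' @export
group_stats <- function(summaries) {
  df <- as.data.frame(summaries)
  stopifnot(all(c("strain", "value") %in% names(df)))
  cnt <- table(df$strain)
  single <- names(cnt)[cnt < 2L]
  if (length(single)) {
    warning("dropping single-replicate group(s): ",
            paste(single, collapse = ", "))
    df <- df[!df$strain %in% single, ]
  }
  if (length(unique(df$strain)) < 2L)
    stop("need at least two groups with >= 2 replicates", call. = FALSE)
  df$strain <- factor(df$strain)
  groups <- data.table::as.data.table(df)[
    , list(n = .N, mean = mean(value),
           sem = stats::sd(value) / sqrt(.N)), by = "strain"]
  data.table::setorderv(groups, "strain")
  if (stats::var(df$value) == 0) {
    lv <- levels(df$strain)
    pairs <- utils::combn(lv, 2, function(p) paste(p[2], p[1], sep = "-"))
    tukey <- data.table::data.table(comparison = pairs, diff = 0,
                                    lwr = 0, upr = 0, p_adj = 1)
    return(list(groups = groups, anova_F = 0, anova_p = 1, tukey = tukey))
  }
  fit <- stats::aov(value ~ strain, data = df)
  an <- summary(fit)[[1]]
  th <- stats::TukeyHSD(fit)$strain
  tukey <- data.table::data.table(comparison = rownames(th),
                                  diff = th[, "diff"], lwr = th[, "lwr"],
                                  upr = th[, "upr"], p_adj = th[, "p adj"])
  list(groups = groups, anova_F = an[["F value"]][1],
       anova_p = an[["Pr(>F)"]][1], tukey = tukey)
}
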