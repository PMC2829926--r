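#' Configuration for the synthetic-study generator
#'
#' Defaults emulate the statistical structure of a 21-subject skeletal-muscle
#' cohort profiled against percentage weight loss: a planted signature of 74
#' positively and 9 negatively trait-correlated genes among ~20,000 expressed
#' genes, with target Pearson correlations drawn from the 0.57-0.82 (positive)
#' and 0.65-0.74 (negative) bands, and a right-skewed covariate spanning
#' -0.5 to 43.8 percent with mean 8.9.
#'
#' @param n_samples number of subjects (default 21).
#' @param n_genes number of genes (default 20000).
#' @param n_pos_signature,n_neg_signature planted positively / negatively
#'   correlated gene counts (defaults 74 and 9).
#' @param target_r_pos,target_r_neg target |Pearson r| bands for planted
#'   genes, per direction.
#' @param covariate_range observed span of the covariate among patients
#'   (percent weight loss), default c(-0.5, 43.8).
#' @param covariate_mean expected patient mean of the covariate (default 8.9).
#' @param n_controls weight-stable non-cancer subjects at exactly 0 percent
#'   weight loss included in the cohort (default 3, as in the emulated
#'   21-subject chip cohort of 3 controls + 18 patients).
#' @param noise_sd residual SD in log2-expression units (default 0.5; studies
#'   of this kind rarely report it, so this is a documented free parameter).
#' @param frac_absent fraction of genes flagged absent on every array,
#'   independent of signature membership (default 0.05).
#' @param n_fg_promoters,n_bg_promoters foreground / background promoter set
#'   sizes (defaults 80 and 800).
#' @param promoter_length promoter window in bp (default 1500).
#' @param planted_motif_rates named list: motif id -> c(fg_rate, bg_rate),
#'   expected planted occurrences per promoter (Poisson). A (0, high) pair
#'   simulates depletion.
#' @param bg_gc background GC fraction for promoter composition (default 0.5,
#'   i.e. uniform 25% per base).
#' @param ct_rep_sd replicate noise SD, in cycles, for simulated qPCR wells
#'   (default 0.15).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_samples = 21, n_genes = 20000,
                       n_pos_signature = 74, n_neg_signature = 9,
                       target_r_pos = c(0.57, 0.82),
                       target_r_neg = c(0.65, 0.74),
                       covariate_range = c(-0.5, 43.8),
                       covariate_mean = 8.9, n_controls = 3,
                       noise_sd = 0.5, frac_absent = 0.05,
                       n_fg_promoters = 80, n_bg_promoters = 800,
                       promoter_length = 1500,
                       planted_motif_rates = list(),
                       bg_gc = 0.5, ct_rep_sd = 0.15, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_pos_signature = as.integer(n_pos_signature),
              n_neg_signature = as.integer(n_neg_signature),
              target_r_pos = target_r_pos, target_r_neg = target_r_neg,
              covariate_range = covariate_range,
              covariate_mean = covariate_mean,
              n_controls = as.integer(n_controls),
              noise_sd = noise_sd, frac_absent = frac_absent,
              n_fg_promoters = as.integer(n_fg_promoters),
              n_bg_promoters = as.integer(n_bg_promoters),
              promoter_length = as.integer(promoter_length),
              planted_motif_rates = planted_motif_rates,
              bg_gc = bg_gc, ct_rep_sd = ct_rep_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid SimConfig field '", field, "': ", why,
                  call. = FALSE)
  chk(cfg$n_samples >= 2, "n_samples", "need >= 2")
  chk(cfg$n_genes >= 1, "n_genes", "need >= 1")
  chk(cfg$n_pos_signature >= 0 && cfg$n_neg_signature >= 0 &&
        cfg$n_pos_signature + cfg$n_neg_signature <= cfg$n_genes,
      "n_pos_signature", "signature sizes must be >= 0 and sum to <= n_genes")
  for (f in c("target_r_pos", "target_r_neg")) {
    r <- cfg[[f]]
    chk(length(r) == 2 && all(r >= 0 & r < 1) && r[1] <= r[2], f,
        "must be an ordered pair of fractions in [0, 1)")
  }
  chk(length(cfg$covariate_range) == 2 &&
        cfg$covariate_range[1] < cfg$covariate_range[2],
      "covariate_range", "lower bound must be below upper bound")
  chk(cfg$n_controls >= 0 && cfg$n_controls <= cfg$n_samples - 2,
      "n_controls", "must leave >= 2 patients")
  chk(cfg$noise_sd > 0, "noise_sd", "must be positive")
  chk(cfg$frac_absent >= 0 && cfg$frac_absent <= 1, "frac_absent",
      "must be a fraction in [0, 1]")
  chk(cfg$bg_gc > 0 && cfg$bg_gc < 1, "bg_gc", "must be in (0, 1)")
  chk(cfg$promoter_length >= 1, "promoter_length", "need >= 1")
  chk(cfg$ct_rep_sd >= 0, "ct_rep_sd", "must be >= 0")
  invisible(cfg)
}

# Right-skewed covariate: both range endpoints are included as samples and
# the remaining n-2 subjects are drawn from a shifted gamma (shape 1.6)
# truncated to the range, with the interior mean chosen so the expected
# cohort mean equals covariate_mean.
draw_covariate <- function(n, range, mean_target) {
  lo <- range[1]; hi <- range[2]
  if (n <= 2) return(range[seq_len(n)])
  interior_mean <- (n * mean_target - lo - hi) / (n - 2)
  interior_mean <- max(interior_mean, lo + 0.05 * (hi - lo))
  shape <- 1.6
  scale <- (interior_mean - lo) / shape
  draws <- numeric(n - 2)
  for (i in seq_len(n - 2)) {
    repeat {
      x <- lo + stats::rgamma(1, shape = shape, scale = scale)
      if (x <= hi) break
    }
    draws[i] <- x
  }
  c(lo, hi, draws)
}

#' Generate a synthetic expression study
#'
#' Builds a log2-expression matrix in which each planted signature gene g
#' follows `baseline_g + slope_g * covariate + N(0, noise_sd)`, with the slope
#' sign set by the planted direction and its magnitude calibrated so the
#' expected Pearson correlation with the covariate equals a target drawn
#' uniformly from the configured band:
#' `slope = r * noise_sd / (sd(covariate) * sqrt(1 - r^2))`.
#' Non-signature genes have zero slope. A fraction `frac_absent` of genes
#' (chosen independently of signature membership) is flagged absent on every
#' array. The clinical table carries percent weight loss, BMI, CRP, the WL/WS
#' label at the 5% weight-loss cut and the SI flag at CRP >= 5 mg/l.
#'
#' @param config a [sim_config()].
#' @return An [expression_study()] with attribute `"truth"`: a data.frame of
#'   the planted genes (gene_id, direction, target_r, slope).
#' @export
generate_expression_study <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_genes

  # cohort = n_controls weight-stable non-cancer subjects at exactly 0%
  # weight loss, plus patients whose weight loss spans covariate_range with
  # mean covariate_mean (right-skewed); controls carry the lower BMI-free /
  # low-CRP profile of the published no-cancer group
  n_ctrl <- config$n_controls
  n_pat <- n - n_ctrl
  wl_pat <- draw_covariate(n_pat, config$covariate_range,
                           config$covariate_mean)
  wl <- c(rep(0, n_ctrl), wl_pat)
  bmi <- round(c(stats::rnorm(n_ctrl, 28.5, 2.5),
                 stats::rnorm(n_pat, 24.4, 3.2)), 1)
  crp <- round(c(stats::rlnorm(n_ctrl, log(2.5), 0.5),
                 stats::rlnorm(n_pat, log(6), 1.2)), 1)
  sample_ids <- sprintf("S%02d", seq_len(n))
  clinical <- data.frame(sample_id = sample_ids,
                         weight_loss_pct = round(wl, 1),
                         bmi = bmi, crp = crp,
                         stringsAsFactors = FALSE)

  gene_ids <- sprintf("G%05d", seq_len(m))
  baseline <- stats::rnorm(m, 7, 1.5)
  # per-gene residual SDs scatter lognormally around noise_sd: real arrays
  # are heteroscedastic, and a common variance would make the empirical
  # Bayes variance prior degenerate
  gene_sd <- config$noise_sd * exp(stats::rnorm(m, 0, 0.25))
  values <- matrix(stats::rnorm(m * n), m, n,
                   dimnames = list(gene_ids, sample_ids)) * gene_sd
  values <- values + baseline

  n_sig <- config$n_pos_signature + config$n_neg_signature
  truth <- data.frame(gene_id = character(0), direction = character(0),
                      target_r = numeric(0), slope = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_sig > 0) {
    idx <- sample.int(m, n_sig)
    dir <- rep(c("positive", "negative"),
               c(config$n_pos_signature, config$n_neg_signature))
    target <- numeric(n_sig)
    pos <- dir == "positive"
    target[pos] <- stats::runif(sum(pos), config$target_r_pos[1],
                                config$target_r_pos[2])
    target[!pos] <- stats::runif(sum(!pos), config$target_r_neg[1],
                                 config$target_r_neg[2])
    slope <- target * gene_sd[idx] /
      (stats::sd(wl) * sqrt(1 - target^2))
    slope[!pos] <- -slope[!pos]
    cov_c <- wl - mean(wl)
    values[idx, ] <- values[idx, ] + slope %o% cov_c
    truth <- data.frame(gene_id = gene_ids[idx], direction = dir,
                        target_r = target, slope = slope,
                        stringsAsFactors = FALSE)
  }

  # per-cell 1% absent sprinkle; only deliberately chosen genes may be
  # all-absent (the sprinkle is repaired so the filter removes exactly them)
  detected <- matrix(stats::runif(m * n) > 0.01, m, n)
  blank <- rowSums(detected) == 0
  if (any(blank)) detected[blank, 1] <- TRUE
  if (config$frac_absent > 0) {
    n_abs <- round(config$frac_absent * m)
    if (n_abs > 0) detected[sample.int(m, n_abs), ] <- FALSE
  }
  dimnames(detected) <- dimnames(values)

  study <- expression_study(values, detected, clinical)
  attr(study, "truth") <- truth
  study
}

#' Generate foreground and background promoter sets
#'
#' Draws i.i.d. background-composition sequences of `promoter_length` bp and,
#' for every motif named in `planted_motif_rates`, inserts occurrences
#' (sampled column-wise from the motif's count-matrix distribution) at uniform
#' random non-overlapping positions, with per-promoter counts Poisson at the
#' configured foreground / background rates. A rate pair `(0, high)`
#' simulates a depleted motif.
#'
#' @param config a [sim_config()].
#' @param motifs list of [load_pfm()] weight matrices; every motif id in
#'   `planted_motif_rates` must appear here.
#' @return list with elements `fg` and `bg`, each a named character vector of
#'   promoter sequences (class `PromoterSet`).
#' @export
generate_promoter_sets <- function(config, motifs) {
  validate_sim_config(config)
  ids <- vapply(motifs, function(m) m$motif_id, character(1))
  names(motifs) <- ids
  rates <- config$planted_motif_rates
  if (length(rates) && !all(names(rates) %in% ids))
    stop("planted_motif_rates names motifs not supplied: ",
         paste(setdiff(names(rates), ids), collapse = ", "))
  for (id in names(rates)) {
    if (ncol(motifs[[id]]$counts) > config$promoter_length)
      stop("motif '", id, "' is longer than promoter_length")
  }
  set.seed(config$seed + 1L)
  base_probs <- c(A = (1 - config$bg_gc) / 2, C = config$bg_gc / 2,
                  G = config$bg_gc / 2, T = (1 - config$bg_gc) / 2)

  make_set <- function(n_seq, prefix, which_rate) {
    seqs <- character(n_seq)
    for (i in seq_len(n_seq)) {
      s <- sample(c("A", "C", "G", "T"), config$promoter_length,
                  replace = TRUE, prob = base_probs)
      occupied <- logical(config$promoter_length)
      for (id in names(rates)) {
        rate <- rates[[id]][which_rate]
        if (rate <= 0) next
        k <- stats::rpois(1, rate)
        wm <- motifs[[id]]
        L <- ncol(wm$counts)
        for (rep_i in seq_len(k)) {
          occ <- sample_motif_occurrence(wm)
          for (try_i in 1:50) {
            pos <- sample.int(config$promoter_length - L + 1, 1)
            if (!any(occupied[pos:(pos + L - 1)])) {
              s[pos:(pos + L - 1)] <- occ
              occupied[pos:(pos + L - 1)] <- TRUE
              break
            }
          }
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- sprintf("%s%04d", prefix, seq_len(n_seq))
    structure(seqs, class = "PromoterSet")
  }

  list(fg = make_set(config$n_fg_promoters, "FG", 1L),
       bg = make_set(config$n_bg_promoters, "BG", 2L))
}

# draw one occurrence string from a count matrix's per-column base frequencies
sample_motif_occurrence <- function(wm) {
  counts <- wm$counts
  bases <- rownames(counts)
  vapply(seq_len(ncol(counts)), function(j) {
    p <- counts[, j]
    if (sum(p) <= 0) p <- rep(1, 4)
    sample(bases, 1, prob = p)
  }, character(1))
}

#' Generate a synthetic qRT-PCR Ct table
#'
#' For every sample and target gene, emits triplicate Ct values following
#' `Ct = ref_Ct + offset - log2_expression + noise`, plus triplicate Cts for
#' an abundant 18S-like reference, so that -deltaCt tracks the gene's planted
#' log-expression. A per-sample machine offset is shared between target and
#' reference wells and therefore cancels in deltaCt.
#'
#' @param config a [sim_config()].
#' @param study the [generate_expression_study()] output the Cts should
#'   reflect.
#' @param target_genes character vector of gene ids present in `study`.
#' @param reference_gene id used for the reference rows (default "RNA18S").
#' @return A data.frame of class `CtTable` with columns
#'   `sample_id, gene_id, replicate, ct` and attribute `reference_gene`.
#' @export
generate_ct_table <- function(config, study, target_genes,
                              reference_gene = "RNA18S") {
  validate_sim_config(config)
  stopifnot(inherits(study, "ExpressionStudy"))
  missing <- setdiff(target_genes, rownames(study$values))
  if (length(missing))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  set.seed(config$seed + 2L)
  samples <- colnames(study$values)
  ref_ct <- 10
  gene_offset <- 18
  rows <- list()
  for (s in seq_along(samples)) {
    machine <- stats::rnorm(1, 0, 0.3)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = samples[s], gene_id = reference_gene, replicate = 1:3,
      ct = ref_ct + machine + stats::rnorm(3, 0, config$ct_rep_sd),
      stringsAsFactors = FALSE)
    for (g in target_genes) {
      mu <- ref_ct + machine + gene_offset - study$values[g, s]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[s], gene_id = g, replicate = 1:3,
        ct = mu + stats::rnorm(3, 0, config$ct_rep_sd),
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  structure(ct, class = c("CtTable", "data.frame"),
            reference_gene = reference_gene)
}

#' Write a SimConfig as a flat key=value file
#' @param config a [sim_config()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sim_config <- function(config, path) {
  flat <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (k == "planted_motif_rates") {
      paste(vapply(names(v), function(id)
        sprintf("%s:%g:%g", id, v[[id]][1], v[[id]][2]), character(1)),
        collapse = ",")
    } else paste(v, collapse = ",")
  }, character(1))
  writeLines(paste0(names(config), "=", flat), path)
  invisible(path)
}
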