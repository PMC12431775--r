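#' Configuration for the synthetic multiome generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: TADs tile each chromosome, one focal gene per TAD, accessible
#' features placed inside TADs, planted feature-to-gene links with signed
#' effects, selector genes with planted regulator motif sites, selector-TF
#' target genes, a conservation track elevated at functional sites, per-group
#' footprint scores, and CUT&Tag peaks covering a configurable fraction of
#' truly bound sites.
#'
#' Six TFs are generated: TF1-TF3 are GABAergic-branch selector TFs (their
#' genes carry planted cCREs and they have planted target genes), TF4 is an
#' early-groups TF, TF5 an early+GABA TF, and TF6 is transcriptionally
#' silent (a decoy). Noise scales (`acc_noise`, `expr_noise`, `fp_noise`)
#' control evidence noise; cell-to-cell accessibility variation (the gamma
#' baseline) is intrinsic signal and is always present.
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Chromosome length in bp (default 2e6).
#' @param tads_per_chrom TADs tiling each chromosome (default 12).
#' @param features_per_tad Accessible features per TAD (default 25).
#' @param feature_width Feature width range in bp (default c(350, 550)).
#' @param cells_per_group Cells per merged cell group (default 40).
#' @param group_labels Ordered cell-group labels (default [default_groups()]).
#' @param n_target_genes Planted selector-target genes (default 12).
#' @param ccres_per_selector Planted linked features per selector gene (4).
#' @param features_per_target Planted linked features per target gene (3).
#' @param effect Planted link effect size (default 1).
#' @param sign_pos_prob Probability a planted target link is positive (2/3).
#' @param target_mix `"mixed"` (half GABA-, half glutamatergic-branch
#'   targets) or `"gaba"` (all GABA-branch).
#' @param base_acc Baseline mean accessibility (default 0.05).
#' @param acc_shape Gamma shape of the accessibility baseline (default 2).
#' @param activation_amp Accessibility increment in a planted feature's
#'   active groups (default 0.5).
#' @param acc_noise,expr_noise,fp_noise Evidence noise scales (defaults
#'   0.02, 0.3, 0.3).
#' @param expr_base,expr_max,expr_K Saturating expression coupling:
#'   `expr = expr_max * u / (u + expr_K)` with
#'   u = max(0, expr_base + sum of sign x effect x accessibility).
#' @param baseline_expr_sd Intrinsic cell-to-cell spread of unplanted genes
#'   (default 0.2; not an evidence-noise scale).
#' @param tf_expr_high,tf_expr_low Profile means for TF genes (2.0 / 0.3).
#' @param pwm_width Motif width range (default c(8, 12)).
#' @param cons_bg_shape Beta shape parameters of background conservation
#'   (default c(1, 6)).
#' @param cons_site_range Conservation range at planted functional sites
#'   (default c(0.55, 0.95): weighted means always exceed 0.5).
#' @param cons_decoy_range Conservation range at low-conservation decoy
#'   sites (default c(0.05, 0.40)).
#' @param cuttag_sensitivity Fraction of truly bound sites covered by a
#'   peak (default 0.9).
#' @param cuttag_fpr_per_mb False peaks per Mb (default 0.5).
#' @param peak_width Peak width range in bp (default c(200, 400)).
#' @param perm_universe_size Size of the candidate-regulator universe used
#'   by the pipeline's permutation test (default 1000).
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_chroms = 2, chrom_length = 2e6, tads_per_chrom = 12,
                         features_per_tad = 25, feature_width = c(350, 550),
                         cells_per_group = 40, group_labels = default_groups(),
                         n_target_genes = 12, ccres_per_selector = 4,
                         features_per_target = 3, effect = 1,
                         sign_pos_prob = 2 / 3, target_mix = "mixed",
                         base_acc = 0.05, acc_shape = 2, activation_amp = 0.5,
                         acc_noise = 0.02, expr_noise = 0.3, fp_noise = 0.3,
                         expr_base = 0.2, expr_max = 3, expr_K = 1,
                         baseline_expr_sd = 0.2,
                         tf_expr_high = 2.0, tf_expr_low = 0.3,
                         pwm_width = c(8, 12),
                         cons_bg_shape = c(1, 6),
                         cons_site_range = c(0.55, 0.95),
                         cons_decoy_range = c(0.05, 0.40),
                         cuttag_sensitivity = 0.9, cuttag_fpr_per_mb = 0.5,
                         peak_width = c(200, 400),
                         perm_universe_size = 1000,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_chroms >= 1, chrom_length > 0, tads_per_chrom >= 1,
            features_per_tad >= 1, cells_per_group >= 3,
            cuttag_sensitivity >= 0, cuttag_sensitivity <= 1,
            sign_pos_prob >= 0, sign_pos_prob <= 1,
            target_mix %in% c("mixed", "gaba"))
  n_tads <- n_chroms * tads_per_chrom
  if (3 + 3 + n_target_genes > n_tads) {
    stop("not enough TADs: need one per gene (", 6 + n_target_genes,
         " genes, ", n_tads, " TADs)")
  }
  slot_w <- (chrom_length / tads_per_chrom) / features_per_tad
  if (slot_w < feature_width[2] + 2) {
    stop("infeasible placement: features exceed TAD capacity")
  }
  structure(cfg, class = "synth_config")
}

#' Zero-evidence-noise variant of a config
#'
#' Sets all evidence-noise scales to zero and makes CUT&Tag coverage of
#' bound sites exhaustive and false-peak free; intrinsic accessibility
#' variation remains (it is the signal being correlated).
#'
#' @param cfg A `synth_config`.
#' @return Modified config.
#' @export
zero_noise_config <- function(cfg) {
  cfg$acc_noise <- 0
  cfg$expr_noise <- 0
  cfg$fp_noise <- 0
  cfg$cuttag_sensitivity <- 1
  cfg$cuttag_fpr_per_mb <- 0
  cfg
}

# informative random PWM: one dominant base per column
random_pwm <- function(width) {
  mat <- vapply(seq_len(width), function(j) {
    dom <- sample.int(4, 1)
    p <- stats::runif(1, 0.7, 0.97)
    rest <- stats::runif(3)
    rest <- rest / sum(rest) * (1 - p)
    col <- numeric(4)
    col[dom] <- p
    col[-dom] <- rest
    col
  }, numeric(4))
  rownames(mat) <- c("A", "C", "G", "T")
  mat
}

#' Simulate a complete synthetic multiome bundle
#'
#' Deterministic given the config seed. See [synth_config()] for the
#' generative model. Planted ground truth (links, regulator sets per gene
#' and group, target sets per TF, bound sites per group) is derived from the
#' realisation, so e.g. `cuttag_sensitivity < 1` shrinks the target truth
#' rather than making it unrecoverable.
#'
#' @param cfg A `synth_config`.
#' @return A `synthetic_bundle` list: genes, tads, features, track, motifs,
#'   sites, footprints, peaks, accessibility, expression, groups,
#'   ground_truth, config.
#' @export
simulate_bundle <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  gaba_groups <- c("GA1_2", "GA3_4", "GA5_6")
  glut_groups <- c("GL1_2", "GL3_4", "GL5")

  # --- TADs tile each chromosome ---
  tads <- do.call(rbind, lapply(chroms, function(ch) {
    bnd <- round(seq(0, cfg$chrom_length, length.out = cfg$tads_per_chrom + 1))
    gintervals(ch, bnd[-length(bnd)], bnd[-1],
               sprintf("TAD_%s_%02d", ch, seq_len(cfg$tads_per_chrom)))
  }))

  # --- genes: one per TAD ---
  tf_names <- paste0("TF", 1:6)
  selectors <- tf_names[1:3]
  tg_ids <- sprintf("TG%02d", seq_len(cfg$n_target_genes))
  n_tads <- nrow(tads)
  n_noise <- n_tads - 6 - cfg$n_target_genes
  gene_ids <- c(tf_names, tg_ids,
                if (n_noise > 0) sprintf("NG%02d", seq_len(n_noise)))
  tad_order <- sample.int(n_tads)
  genes <- data.frame(gene_id = gene_ids,
                      chrom = tads$chrom[tad_order[seq_along(gene_ids)]],
                      tss = NA_real_, strand = sample(c("+", "-"), length(gene_ids), TRUE),
                      tad = tads$name[tad_order[seq_along(gene_ids)]],
                      stringsAsFactors = FALSE)
  ti <- match(genes$tad, tads$name)
  genes$tss <- round(tads$start[ti] + (tads$end[ti] - tads$start[ti]) *
                       stats::runif(nrow(genes), 0.3, 0.7))

  # --- features placed in equal slots inside each TAD ---
  feats <- do.call(rbind, lapply(seq_len(n_tads), function(k) {
    slot <- (tads$end[k] - tads$start[k]) / cfg$features_per_tad
    w <- round(stats::runif(cfg$features_per_tad, cfg$feature_width[1], cfg$feature_width[2]))
    off <- floor(stats::runif(cfg$features_per_tad, 0, slot - w - 1))
    st <- round(tads$start[k] + (seq_len(cfg$features_per_tad) - 1) * slot + off)
    data.frame(chrom = tads$chrom[k], start = st, end = st + w, tad = tads$name[k],
               stringsAsFactors = FALSE)
  }))
  feats$name <- sprintf("F%05d", seq_len(nrow(feats)))
  features <- gintervals(feats$chrom, feats$start, feats$end, feats$name)
  features$tad <- feats$tad

  # --- planted links ---
  # every planted gene gets its own activation-group pattern (anchored at
  # GA1_2 or GL1_2) so features of different genes are only weakly
  # cross-correlated and the matched linkage background stays informative
  gene_pattern <- list(TF1 = gaba_groups,
                       TF2 = c("GA1_2", "GA3_4"),
                       TF3 = c("GA1_2", "GA5_6"))
  for (i in seq_along(tg_ids)) {
    gaba_g <- i %% 2 == 1 || cfg$target_mix == "gaba"
    extra <- if (gaba_g) c("GA3_4", "GA5_6") else c("GL3_4", "GL5")
    anchor <- if (gaba_g) "GA1_2" else "GL1_2"
    k <- sample(0:2, 1)
    gene_pattern[[tg_ids[i]]] <- c(anchor, sample(extra, k))
  }
  pick_feats <- function(gene_id, n) {
    tad <- genes$tad[match(gene_id, genes$gene_id)]
    sample(features$name[features$tad == tad], n)
  }
  links <- list()
  for (s in selectors) {
    links[[s]] <- data.frame(feature_id = pick_feats(s, cfg$ccres_per_selector),
                             gene_id = s, sign = "+", effect = cfg$effect,
                             stringsAsFactors = FALSE)
  }
  for (g in tg_ids) {
    sgn <- ifelse(stats::runif(cfg$features_per_target) < cfg$sign_pos_prob, "+", "-")
    if (cfg$target_mix == "gaba") sgn[] <- "+"
    links[[g]] <- data.frame(feature_id = pick_feats(g, cfg$features_per_target),
                             gene_id = g, sign = sgn, effect = cfg$effect,
                             stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, links)
  rownames(links) <- NULL

  # --- TF expression programmes ---
  # selector TF expression follows its own coupled pattern; helper TFs get
  # fixed profiles (TF4 early, TF5 early+GABA, TF6 silent decoy)
  expressed_groups <- list(TF1 = gene_pattern$TF1, TF2 = gene_pattern$TF2,
                           TF3 = gene_pattern$TF3,
                           TF4 = c("PRO1_2", "CO1_2"),
                           TF5 = c("CO1_2", "GA1_2"),
                           TF6 = character(0))

  # --- motifs ---
  motifs <- lapply(tf_names, function(tf) {
    w <- sample(seq(cfg$pwm_width[1], cfg$pwm_width[2]), 1)
    id <- paste0(tf, ".M1")
    list(motif_id = id, tf_name = tf, mat = random_pwm(w))
  })
  names(motifs) <- vapply(motifs, `[[`, "", "motif_id")

  # --- motif sites ---
  regulator_sets <- list(TF1 = c("TF1", "TF2", "TF4", "TF5"),
                         TF2 = c("TF2", "TF3", "TF4", "TF5"),
                         TF3 = c("TF1", "TF3", "TF4", "TF5"))
  target_sets <- list(TF1 = tg_ids[seq_len(min(8, length(tg_ids)))],
                      TF2 = tg_ids[c(1:4, 9, 10)[c(1:4, 9, 10) <= length(tg_ids)]],
                      TF3 = tg_ids[c(3:6, 11, 12)[c(3:6, 11, 12) <= length(tg_ids)]])
  site_rows <- list()
  slot_used <- new.env()
  place_site <- function(tf, feature_id, conserved, bound_tf) {
    # sequential 30-bp slots from offset 20 keep sites disjoint
    k <- mget(feature_id, envir = slot_used, ifnotfound = 0L)[[1]]
    assign(feature_id, k + 1L, envir = slot_used)
    fi <- match(feature_id, features$name)
    w <- ncol(motifs[[paste0(tf, ".M1")]]$mat)
    st <- features$start[fi] + 20 + k * 30
    if (st + w > features$end[fi]) stop("feature too small for site placement")
    bound_groups <- if (is.na(bound_tf)) character(0) else expressed_groups[[bound_tf]]
    data.frame(tf_name = tf, motif_id = paste0(tf, ".M1"),
               chrom = features$chrom[fi], start = st, end = st + w,
               strand = sample(c("+", "-"), 1), feature_id = feature_id,
               conserved_band = conserved,
               bound_groups = paste(bound_groups, collapse = ","),
               stringsAsFactors = FALSE)
  }
  for (s in selectors) {
    sel_feats <- links$feature_id[links$gene_id == s]
    for (t in regulator_sets[[s]]) {
      site_rows[[length(site_rows) + 1L]] <-
        place_site(t, sample(sel_feats, 1), conserved = TRUE, bound_tf = t)
    }
    # decoys: low-conservation bound TF5; unbound TF4; silent TF6
    site_rows[[length(site_rows) + 1L]] <-
      place_site("TF5", sample(sel_feats, 1), conserved = FALSE, bound_tf = "TF5")
    site_rows[[length(site_rows) + 1L]] <-
      place_site("TF4", sample(sel_feats, 1), conserved = TRUE, bound_tf = NA)
    site_rows[[length(site_rows) + 1L]] <-
      place_site("TF6", sample(sel_feats, 1), conserved = TRUE, bound_tf = "TF6")
  }
  for (t in selectors) {
    for (g in target_sets[[t]]) {
      f <- sample(links$feature_id[links$gene_id == g], 1)
      site_rows[[length(site_rows) + 1L]] <- place_site(t, f, TRUE, bound_tf = t)
    }
    # target decoys: low-conservation bound sites in own target features,
    # conserved unbound sites in non-target features
    own <- links$feature_id[links$gene_id %in% target_sets[[t]]]
    other <- links$feature_id[links$gene_id %in% setdiff(tg_ids, target_sets[[t]])]
    for (f in sample(own, min(2, length(own)))) {
      site_rows[[length(site_rows) + 1L]] <- place_site(t, f, FALSE, bound_tf = t)
    }
    for (f in sample(other, min(2, length(other)))) {
      site_rows[[length(site_rows) + 1L]] <- place_site(t, f, TRUE, bound_tf = NA)
    }
  }
  sites <- do.call(rbind, site_rows)
  sites$site_id <- sprintf("S%05d", seq_len(nrow(sites)))
  sites <- sites[c("site_id", "motif_id", "tf_name", "chrom", "start", "end",
                   "strand", "feature_id", "conserved_band", "bound_groups")]

  # --- conservation track: per-base scores over feature bases ---
  track_rows <- lapply(seq_len(nrow(features)), function(i) {
    pos <- seq.int(features$start[i], features$end[i] - 1)
    data.frame(chrom = features$chrom[i], start = pos, end = pos + 1,
               score = stats::rbeta(length(pos), cfg$cons_bg_shape[1], cfg$cons_bg_shape[2]),
               stringsAsFactors = FALSE)
  })
  track_df <- do.call(rbind, track_rows)
  key <- paste(track_df$chrom, track_df$start)
  for (i in seq_len(nrow(sites))) {
    pos <- seq.int(sites$start[i], sites$end[i] - 1)
    rng <- if (sites$conserved_band[i]) cfg$cons_site_range else cfg$cons_decoy_range
    track_df$score[match(paste(sites$chrom[i], pos), key)] <-
      stats::runif(length(pos), rng[1], rng[2])
  }
  track <- cons_track(track_df)

  # --- footprints: positive draws for bound (site, group) pairs ---
  grp <- cfg$group_labels
  fp <- expand.grid(site_id = sites$site_id, cell_group = grp,
                    stringsAsFactors = FALSE)
  bg_list <- strsplit(sites$bound_groups[match(fp$site_id, sites$site_id)], ",", fixed = TRUE)
  is_bound <- mapply(function(b, g) g %in% b, bg_list, fp$cell_group)
  score <- numeric(nrow(fp))
  score[is_bound] <- 0.2 + cfg$fp_noise * abs(stats::rnorm(sum(is_bound)))
  nz <- !is_bound
  zero_draw <- stats::runif(sum(nz)) < 0.5
  neg <- numeric(sum(nz))
  neg[!zero_draw] <- -(0.1 + cfg$fp_noise * abs(stats::rnorm(sum(!zero_draw))))
  score[nz] <- neg
  footprints <- data.frame(site_id = fp$site_id, cell_group = fp$cell_group,
                           footprint_score = score, bound = score > 0,
                           stringsAsFactors = FALSE)

  # --- CUT&Tag peaks ---
  truly_bound <- sites[nzchar(sites$bound_groups), , drop = FALSE]
  peaks <- list()
  covered_sites <- character(0)
  genome_mb <- cfg$n_chroms * cfg$chrom_length / 1e6
  for (tf in tf_names) {
    ts <- truly_bound[truly_bound$tf_name == tf, , drop = FALSE]
    cov <- if (nrow(ts)) stats::runif(nrow(ts)) < cfg$cuttag_sensitivity else logical(0)
    covered_sites <- c(covered_sites, ts$site_id[cov])
    pk <- NULL
    if (any(cov)) {
      mid <- (ts$start[cov] + ts$end[cov]) / 2
      pw <- round(stats::runif(sum(cov), cfg$peak_width[1], cfg$peak_width[2]))
      pk <- data.frame(chrom = ts$chrom[cov],
                       start = pmax(0, round(mid - pw / 2)),
                       end = round(mid + pw / 2), stringsAsFactors = FALSE)
    }
    n_false <- stats::rpois(1, cfg$cuttag_fpr_per_mb * genome_mb)
    if (n_false > 0) {
      pw <- round(stats::runif(n_false, cfg$peak_width[1], cfg$peak_width[2]))
      st <- floor(stats::runif(n_false, 0, cfg$chrom_length - pw))
      pk <- rbind(pk, data.frame(chrom = sample(chroms, n_false, TRUE),
                                 start = st, end = st + pw, stringsAsFactors = FALSE))
    }
    peaks[[tf]] <- if (is.null(pk)) {
      gintervals(character(0), numeric(0), numeric(0))
    } else {
      pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
      gintervals(pk$chrom, pk$start, pk$end,
                 sprintf("%s_peak_%03d", tf, seq_len(nrow(pk))))
    }
  }

  # --- cells and accessibility ---
  n_cells <- length(grp) * cfg$cells_per_group
  cell_ids <- sprintf("C%04d", seq_len(n_cells))
  cell_grp <- rep(grp, each = cfg$cells_per_group)
  groups <- cell_group_map(cell_ids, cell_grp, levels = grp)
  nf <- nrow(features)
  acc <- matrix(stats::rgamma(n_cells * nf, shape = cfg$acc_shape,
                              scale = cfg$base_acc / cfg$acc_shape),
                nrow = n_cells, ncol = nf,
                dimnames = list(cell_ids, features$name))
  # negative-effect features are accessible in the mirrored branch: a
  # repressive element open where the gene is off gives the planted link its
  # negative correlation instead of cancelling against the positive features
  mirror_group <- c(GA1_2 = "GL1_2", GA3_4 = "GL3_4", GA5_6 = "GL5",
                    GL1_2 = "GA1_2", GL3_4 = "GA3_4", GL5 = "GA5_6")
  feat_pattern <- lapply(seq_len(nrow(links)), function(i) {
    p <- gene_pattern[[links$gene_id[i]]]
    if (links$sign[i] == "-") unname(mirror_group[p]) else p
  })
  names(feat_pattern) <- links$feature_id
  for (f in links$feature_id) {
    on <- cell_grp %in% feat_pattern[[f]]
    acc[on, f] <- acc[on, f] + cfg$activation_amp
  }
  if (cfg$acc_noise > 0) {
    acc <- pmax(acc + cfg$acc_noise * stats::rnorm(length(acc)), 0)
  }

  # --- expression ---
  expr <- matrix(0, n_cells, nrow(genes), dimnames = list(cell_ids, genes$gene_id))
  planted_genes <- unique(links$gene_id)
  for (g in planted_genes) {
    d <- links[links$gene_id == g, , drop = FALSE]
    s <- rowSums(sweep(acc[, d$feature_id, drop = FALSE], 2,
                       ifelse(d$sign == "+", 1, -1) * d$effect, `*`))
    r <- pmax(0, cfg$expr_base + s)
    expr[, g] <- cfg$expr_max * r / (r + cfg$expr_K)
  }
  for (tf in c("TF4", "TF5", "TF6")) {
    mu <- ifelse(cell_grp %in% expressed_groups[[tf]], cfg$tf_expr_high, cfg$tf_expr_low)
    expr[, tf] <- mu
  }
  noise_genes <- setdiff(genes$gene_id, c(planted_genes, "TF4", "TF5", "TF6"))
  for (g in noise_genes) {
    expr[, g] <- stats::runif(1, 0.2, 0.8) +
      cfg$baseline_expr_sd * stats::rnorm(n_cells)
  }
  if (cfg$expr_noise > 0) {
    expr <- expr + cfg$expr_noise * stats::rnorm(length(expr))
  }
  expr <- pmax(expr, 0)

  # --- ground truth derived from the planted realisation ---
  site_bound <- strsplit(sites$bound_groups, ",", fixed = TRUE)
  bound_truth <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    if (!nzchar(sites$bound_groups[i])) return(NULL)
    data.frame(site_id = sites$site_id[i], cell_group = site_bound[[i]],
               stringsAsFactors = FALSE)
  }))
  sel_feats_all <- links[links$gene_id %in% selectors, , drop = FALSE]
  reg_truth <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    f <- sites$feature_id[i]
    gi <- sel_feats_all$gene_id[match(f, sel_feats_all$feature_id)]
    if (is.na(gi) || !sites$conserved_band[i] || !nzchar(sites$bound_groups[i])) return(NULL)
    data.frame(gene_id = gi, cell_group = site_bound[[i]],
               tf_name = sites$tf_name[i], stringsAsFactors = FALSE)
  }))
  if (!is.null(reg_truth)) reg_truth <- unique(reg_truth)
  tgt_truth <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    f <- sites$feature_id[i]
    gi <- links$gene_id[match(f, links$feature_id)]
    if (is.na(gi) || !sites$conserved_band[i]) return(NULL)
    if (!any(site_bound[[i]] %in% c("GA1_2", "GL1_2"))) return(NULL)
    if (!sites$site_id[i] %in% covered_sites) return(NULL)
    data.frame(tf = sites$tf_name[i], gene_id = gi, site_id = sites$site_id[i],
               feature_id = f, stringsAsFactors = FALSE)
  }))
  ground_truth <- list(
    links = links,
    regulators = reg_truth,
    targets = if (is.null(tgt_truth)) NULL else unique(tgt_truth[c("tf", "gene_id")]),
    target_sites = tgt_truth,
    bound = bound_truth,
    expressed_groups = expressed_groups,
    gene_pattern = gene_pattern,
    selectors = selectors
  )

  structure(list(genes = genes, tads = tads, features = features,
                 track = track, motifs = motifs,
                 sites = sites[c("site_id", "motif_id", "tf_name", "chrom",
                                 "start", "end", "strand", "feature_id")],
                 footprints = footprints, peaks = peaks,
                 accessibility = acc, expression = expr, groups = groups,
                 ground_truth = ground_truth, config = cfg),
            class = "synthetic_bundle")
}

#' Write a bundle to standard-format files
#'
#' Emits BED/bedGraph/TSV/MTX/MEME files plus `ground_truth.json`,
#' `config.yaml`, and a `manifest.tsv` with md5 checksums.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (file, md5), invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  p <- function(...) file.path(dir, ...)
  write_gene_table(bundle$genes, p("genes.tsv"))
  write_bed(bundle$tads, p("tads.bed"))
  write_bed(bundle$features, p("features.bed"))
  write_tsv_table(data.frame(feature_id = bundle$features$name,
                             tad = bundle$features$tad), p("feature_tads.tsv"))
  write_bedgraph(bundle$track, p("conservation.bedgraph"))
  write_meme(bundle$motifs, p("motifs.meme"))
  write_tsv_table(bundle$sites, p("sites.tsv"))
  write_tsv_table(bundle$footprints, p("footprints.tsv"))
  dir.create(p("peaks"), showWarnings = FALSE)
  for (tf in names(bundle$peaks)) {
    write_bed(bundle$peaks[[tf]], p("peaks", paste0(tf, ".bed")))
  }
  write_matrix_mtx(bundle$accessibility, p("accessibility"))
  write_matrix_mtx(bundle$expression, p("expression"))
  write_tsv_table(bundle$groups, p("cell_groups.tsv"))
  jsonlite::write_json(bundle$ground_truth, p("ground_truth.json"),
                       dataframe = "columns", null = "null", digits = NA)
  yaml::write_yaml(unclass(bundle$config), p("config.yaml"))
  files <- sort(c(list.files(dir, recursive = TRUE)))
  files <- files[files != "manifest.tsv"]
  manifest <- data.frame(file = files,
                         md5 = as.character(tools::md5sum(file.path(dir, files))),
                         row.names = NULL, stringsAsFactors = FALSE)
  write_tsv_table(manifest, p("manifest.tsv"))
  invisible(manifest)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `synthetic_bundle` (matrices dense; ground truth from JSON).
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  genes <- utils::read.table(p("genes.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  features <- parse_bed(p("features.bed"))
  ft <- read_tsv_table(p("feature_tads.tsv"))
  features$tad <- ft$tad[match(features$name, ft$feature_id)]
  gt <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
  if (!is.null(gt$gene_pattern)) gt$gene_pattern <- lapply(gt$gene_pattern, unlist)
  if (!is.null(gt$expressed_groups)) {
    gt$expressed_groups <- lapply(gt$expressed_groups, function(x) unlist(x) %||% character(0))
  }
  cfgl <- yaml::read_yaml(p("config.yaml"))
  groups_df <- read_cell_groups(p("cell_groups.tsv"), levels = cfgl$group_labels)
  peaks <- list()
  for (f in list.files(p("peaks"), full.names = FALSE)) {
    peaks[[sub("\\.bed$", "", f)]] <- parse_bed(p("peaks", f))
  }
  structure(list(genes = genes, tads = parse_bed(p("tads.bed")),
                 features = features, track = parse_bedgraph(p("conservation.bedgraph")),
                 motifs = read_meme(p("motifs.meme")),
                 sites = read_tsv_table(p("sites.tsv")),
                 footprints = read_tsv_table(p("footprints.tsv")),
                 peaks = peaks,
                 accessibility = read_matrix_mtx(p("accessibility")),
                 expression = read_matrix_mtx(p("expression")),
                 groups = groups_df,
                 ground_truth = gt, config = cfgl),
            class = "synthetic_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a segmentation ROI table for laminar quantification
#'
#' Cells are placed at radial distances from a known ventricular-surface
#' circle; three channels carry distance-dependent dot counts peaking at
#' configurable depths, so apical-basal expression ordering is recoverable.
#'
#' @param n_cells Cells per replicate (default 300).
#' @param n_replicates Biological replicates (default 3).
#' @param circle List with centre and radius (defaults to centre (0, 0),
#'   radius 100).
#' @param cell_radius Mean cell radius in pixels (default 5).
#' @param peak_depth Per-channel peak depth in average-diameter units
#'   (default c(1, 3, 5)).
#' @param seed Integer seed.
#' @return List: `rois` data.frame and the `circle` used.
#' @export
simulate_roi_table <- function(n_cells = 300, n_replicates = 3,
                               circle = list(centre = c(0, 0), radius = 100),
                               cell_radius = 5, peak_depth = c(1, 3, 5),
                               seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    depth <- stats::runif(n_cells, 0, 8)            # in avg-diameter units
    theta <- stats::runif(n_cells, 0, 2 * pi)
    rad <- circle$radius + depth * 2 * cell_radius
    x <- circle$centre[1] + rad * cos(theta)
    y <- circle$centre[2] + rad * sin(theta)
    area <- pi * (cell_radius * stats::runif(n_cells, 0.85, 1.15))^2
    ch <- sapply(peak_depth, function(pk) {
      stats::rpois(n_cells, 2 + 20 * exp(-(depth - pk)^2 / 2))
    })
    colnames(ch) <- paste0("ch", seq_along(peak_depth))
    rows[[r]] <- data.frame(roi_id = sprintf("R%d_%04d", r, seq_len(n_cells)),
                            x = x, y = y, area = area,
                            image = sprintf("img%d", r),
                            replicate = sprintf("rep%d", r),
                            ch, stringsAsFactors = FALSE)
  }
  list(rois = do.call(rbind, rows), circle = circle,
       depth_unit = 2 * cell_radius)
}
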