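# Synthetic multi-study benchmark generator with known ground truth.
#
# A "world" holds latent cell and drug embeddings plus per-entity biases; the
# clean response surface is a low-rank bilinear form squashed into [0, 1],
#   f(c, d) = plogis(gain * u_c . v_d + b_c + b_d),
# the simplest structure that lets linear and tree baselines learn partially
# while leaving headroom. Studies draw overlapping subsets of cells and drugs
# (a deterministic shared-pool prefix plus disjoint study-private blocks, so
# pairwise entity coverage is controlled exactly) and observe
#   auc = clip(a_s * f + b_s + noise, 0, 1),
# a per-study affine assay distortion plus mildly heteroscedastic noise —
# a minimal stand-in for differing viability assay protocols across studies.

#' Per-study specification
#'
#' @param name Study label.
#' @param n_cells,n_drugs Entity counts for the study.
#' @param drug_overlap,cell_overlap Fraction of the study's drugs/cells drawn
#'   from the shared reference pool (in `[0, 1]`); the remainder comes from a
#'   study-private block, so two studies share exactly the overlap of their
#'   pool prefixes.
#' @return A `study_spec` list.
#' @export
study_spec <- function(name, n_cells, n_drugs, drug_overlap = 0.6,
                       cell_overlap = 0.8) {
  stopifnot(is_count(n_cells), is_count(n_drugs),
            drug_overlap >= 0, drug_overlap <= 1,
            cell_overlap >= 0, cell_overlap <= 1)
  structure(list(name = name, n_cells = n_cells, n_drugs = n_drugs,
                 drug_overlap = drug_overlap, cell_overlap = cell_overlap),
            class = "study_spec")
}

#' Default desk-scale study roster
#'
#' Five studies with decreasing sizes (mirroring the heterogeneity of public
#' drug screens: one large screen down to a small 15-drug panel).
#'
#' @return List of five [study_spec()] objects.
#' @export
default_study_specs <- function() {
  sizes_c <- c(250, 200, 160, 140, 120)
  sizes_d <- c(70, 45, 35, 25, 15)
  lapply(1:5, function(i) {
    study_spec(paste0("study_", i), sizes_c[i], sizes_d[i])
  })
}

#' Synthetic world configuration
#'
#' @param n_cells_total,n_drugs_total Global entity pool sizes.
#' @param latent_dim Dimension of the latent embeddings (>= 1).
#' @param n_noise_cell,n_noise_drug Count of uninformative noise features
#'   appended to the omics / drug descriptor matrices.
#' @param noise_sd Response noise scale (AUC units).
#' @param assay_shift_sd Magnitude of the per-study affine distortion
#'   (`a_s = 1 + N(0, sd)`, `b_s = N(0, sd / 2)`); 0 disables assay shifts.
#' @param completeness Fraction of the cell x drug grid measured per study.
#' @param study_specs List of [study_spec()]s.
#' @param seed Integer seed; the whole world is deterministic given it.
#' @return A `synth_world_config` list.
#' @export
synth_world_config <- function(n_cells_total = 600, n_drugs_total = 180,
                               latent_dim = 10, n_noise_cell = 30,
                               n_noise_drug = 10, noise_sd = 0.05,
                               assay_shift_sd = 0.15, completeness = 0.6,
                               study_specs = default_study_specs(),
                               seed = 1) {
  if (!is_count(latent_dim)) {
    drp_error("'latent_dim' must be a positive integer", "drp_config_error")
  }
  stopifnot(is_count(n_cells_total), is_count(n_drugs_total),
            noise_sd >= 0, assay_shift_sd >= 0,
            completeness > 0, completeness <= 1, length(study_specs) >= 1)
  structure(list(n_cells_total = n_cells_total, n_drugs_total = n_drugs_total,
                 latent_dim = latent_dim, n_noise_cell = n_noise_cell,
                 n_noise_drug = n_noise_drug, noise_sd = noise_sd,
                 assay_shift_sd = assay_shift_sd, completeness = completeness,
                 study_specs = study_specs, seed = as.integer(seed)),
            class = "synth_world_config")
}

# Deterministic pool-prefix + private-block entity assignment.
assign_entities <- function(n_total, counts, overlaps, what) {
  k <- round(overlaps * counts)         # pool prefix taken by each study
  pool <- max(k)
  private <- counts - k
  need <- pool + sum(private)
  if (need > n_total) {
    drp_error(sprintf(
      "requested %s overlap impossible: need %d entities, pool has %d",
      what, need, n_total), "drp_config_error")
  }
  offsets <- pool + cumsum(c(0, utils::head(private, -1)))
  lapply(seq_along(counts), function(j) {
    c(seq_len(k[j]),
      if (private[j] > 0) offsets[j] + seq_len(private[j]) else integer(0))
  })
}

#' Simulate a synthetic multi-study world
#'
#' Draws spherical Gaussian embeddings and biases, evaluates the clean
#' response surface `f` on the full cell x drug grid, fixes per-study assay
#' shift parameters, and assigns each study its cells and drugs. Everything
#' is deterministic given the config seed.
#'
#' @param config A [synth_world_config()].
#' @return An object of class `synth_world`.
#' @export
simulate_world <- function(config = synth_world_config()) {
  stopifnot(inherits(config, "synth_world_config"))
  nc <- config$n_cells_total
  nd <- config$n_drugs_total
  k <- config$latent_dim
  ns <- length(config$study_specs)
  world <- with_rng_seed(config$seed, {
    sd_lat <- k^(-0.25)   # makes var(u . v) approximately 1
    u <- matrix(stats::rnorm(nc * k, sd = sd_lat), nc, k)
    v <- matrix(stats::rnorm(nd * k, sd = sd_lat), nd, k)
    b_c <- stats::rnorm(nc, sd = 0.3)
    b_d <- stats::rnorm(nd, sd = 0.6)
    cell_noise <- matrix(stats::rnorm(nc * config$n_noise_cell), nc)
    drug_noise <- matrix(stats::rnorm(nd * config$n_noise_drug), nd)
    proj <- matrix(stats::rnorm(k * 64), k, 64)
    drug_fp <- (v %*% proj + matrix(stats::rnorm(nd * 64, sd = 0.1), nd) > 0) * 1L
    a_s <- 1 + stats::rnorm(ns, sd = config$assay_shift_sd)
    b_s <- stats::rnorm(ns, sd = config$assay_shift_sd / 2)
    f <- stats::plogis(1.2 * tcrossprod(u, v) + outer(b_c, b_d, `+`))
    list(u = u, v = v, b_c = b_c, b_d = b_d, cell_noise = cell_noise,
         drug_noise = drug_noise, drug_fp = drug_fp, a_s = a_s, b_s = b_s,
         f = f)
  })
  cell_ids <- sprintf("cell_%04d", seq_len(nc))
  drug_ids <- sprintf("drug_%04d", seq_len(nd))
  specs <- config$study_specs
  cells_by_study <- assign_entities(
    nc, vapply(specs, `[[`, 0, "n_cells"),
    vapply(specs, `[[`, 0, "cell_overlap"), "cell")
  drugs_by_study <- assign_entities(
    nd, vapply(specs, `[[`, 0, "n_drugs"),
    vapply(specs, `[[`, 0, "drug_overlap"), "drug")
  structure(list(config = config, cell_ids = cell_ids, drug_ids = drug_ids,
                 u = world$u, v = world$v, b_c = world$b_c, b_d = world$b_d,
                 cell_noise = world$cell_noise, drug_noise = world$drug_noise,
                 drug_fp = world$drug_fp, f = world$f,
                 a_s = world$a_s, b_s = world$b_s,
                 cells_by_study = cells_by_study,
                 drugs_by_study = drugs_by_study),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world> %d cells x %d drugs, latent dim %d, %d studies\n",
              nrow(x$u), nrow(x$v), ncol(x$u), length(x$config$study_specs)))
  invisible(x)
}

#' Emit one study as a benchmark bundle
#'
#' Samples `completeness * n_cells * n_drugs` (cell, drug) pairs from the
#' study's grid, computes noisy shifted AUC responses, and packages them with
#' the study's omics features (latent embedding columns padded with noise
#' features), descriptor-like drug features (latent plus noise columns),
#' pseudo-fingerprint bits, and `n_splits` reproducible splits.
#'
#' @param world A [simulate_world()] result.
#' @param study Study index or name.
#' @param n_splits Number of splits to attach (default 10).
#' @return An [assemble_bundle()] object; attribute `truth` holds the clean
#'   `f` values of the emitted samples.
#' @export
emit_study <- function(world, study, n_splits = 10) {
  stopifnot(inherits(world, "synth_world"))
  cfg <- world$config
  names_s <- vapply(cfg$study_specs, `[[`, "", "name")
  j <- if (is.character(study)) match(study, names_s) else as.integer(study)
  if (is.na(j) || j < 1 || j > length(names_s)) {
    drp_error(paste0("unknown study: ", study), "drp_config_error")
  }
  cells <- world$cells_by_study[[j]]
  drugs <- world$drugs_by_study[[j]]
  grid <- expand.grid(cell = cells, drug = drugs)
  n_samples <- max(round(cfg$completeness * nrow(grid)), n_splits)
  seed_j <- derive_seed(cfg$seed, paste0("emit/", names_s[j]))
  bundle <- with_rng_seed(seed_j, {
    take <- sort(sample(nrow(grid), n_samples))
    g <- grid[take, ]
    f <- world$f[cbind(g$cell, g$drug)]
    noise <- stats::rnorm(n_samples, sd = cfg$noise_sd * (0.5 + f))
    auc <- pmin(pmax(world$a_s[j] * f + world$b_s[j] + noise, 0), 1)
    resp <- response_table(
      data.frame(cell_id = world$cell_ids[g$cell],
                 drug_id = world$drug_ids[g$drug], auc = auc),
      dataset_name = names_s[j])
    omics <- cbind(world$u, world$cell_noise)
    colnames(omics) <- c(paste0("latent_", seq_len(ncol(world$u))),
                         paste0("noise_", seq_len(ncol(world$cell_noise))))
    rownames(omics) <- world$cell_ids
    desc <- cbind(world$v, world$drug_noise)
    colnames(desc) <- c(paste0("vlat_", seq_len(ncol(world$v))),
                        paste0("vnoise_", seq_len(ncol(world$drug_noise))))
    rownames(desc) <- world$drug_ids
    fp <- world$drug_fp
    colnames(fp) <- paste0("fp_", seq_len(ncol(fp)))
    rownames(fp) <- world$drug_ids
    splits <- generate_splits(nrow(resp), n_splits,
                              seed = derive_seed(seed_j, "splits"))
    b <- assemble_bundle(resp,
                         omics[world$cell_ids[cells], , drop = FALSE],
                         list(descriptor = desc[world$drug_ids[drugs], , drop = FALSE],
                              fingerprint = fp[world$drug_ids[drugs], , drop = FALSE]),
                         splits = splits, name = names_s[j])
    attr(b, "truth") <- f
    b
  })
  bundle
}

#' Emit every study of a world
#'
#' @param world A [simulate_world()] result.
#' @param n_splits Splits per study.
#' @return Named list of bundles, one per study.
#' @export
emit_all_studies <- function(world, n_splits = 10) {
  names_s <- vapply(world$config$study_specs, `[[`, "", "name")
  stats::setNames(lapply(seq_along(names_s), emit_study, world = world,
                         n_splits = n_splits), names_s)
}

#' Random Hill-curve parameter sets for recovery experiments
#'
#' EC50 log-uniform on `[1e-9, 1e-5]` M, slope uniform on `[0.5, 3]`,
#' `e_inf` uniform on `[0, 0.5]`.
#'
#' @param n Number of parameter sets.
#' @param seed Integer seed.
#' @return Data frame `cell_id`, `drug_id`, `ec50`, `slope`, `e_inf`.
#' @export
sample_hill_params <- function(n, seed = 1) {
  with_rng_seed(seed, {
    data.frame(
      cell_id = sprintf("cell_%04d", seq_len(n)),
      drug_id = sprintf("drug_%04d", seq_len(n)),
      ec50 = 10^stats::runif(n, -9, -5),
      slope = stats::runif(n, 0.5, 3),
      e_inf = stats::runif(n, 0, 0.5),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate raw dose-response measurements
#'
#' Evaluates the Hill-slope curve of each (cell, drug) parameter set on a
#' dose grid and adds Gaussian viability noise, producing the long-format
#' table consumed by [fit_response_data()]. The generating parameters are
#' attached for recovery tests.
#'
#' @param truth Data frame from [sample_hill_params()] (columns `cell_id`,
#'   `drug_id`, `ec50`, `slope`, `e_inf`).
#' @param doses Molar dose grid, within `[1e-11, 1e-3]` M.
#' @param noise_sd Viability noise standard deviation (0 for noiseless).
#' @param seed Integer seed.
#' @return Data frame `cell_id`, `drug_id`, `dose_M`, `viability` with
#'   attribute `truth`.
#' @export
simulate_dose_response <- function(truth, doses, noise_sd = 0, seed = 1) {
  stopifnot(all(c("cell_id", "drug_id", "ec50", "slope", "e_inf") %in%
                  names(truth)))
  if (any(doses < 1e-11 | doses > 1e-3)) {
    drp_error("doses must lie within [1e-11, 1e-3] M", "drp_config_error")
  }
  out <- with_rng_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      p <- hill_params(truth$ec50[i], truth$slope[i], truth$e_inf[i])
      v <- hill_viability(p, doses)
      if (noise_sd > 0) v <- v + stats::rnorm(length(doses), sd = noise_sd)
      data.frame(cell_id = truth$cell_id[i], drug_id = truth$drug_id[i],
                 dose_M = doses, viability = v, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  attr(out, "truth") <- truth
  out
}
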