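#' Study condition labels
#'
#' The five conditions of the replicated live-imaging design: Rab8a in
#' wild-type cones, rods, Rab8ba in wild-type rods, and both paralogs in
#' mutant rods.
#' @return character vector of condition labels.
#' @export
study_conditions <- function() {
  c("wt Rab8a cones", "wt Rab8a rods", "wt Rab8ba rods",
    "mut Rab8a rods", "mut Rab8ba rods")
}

#' Generator presets for a study condition
#'
#' Wild-type conditions use the default motion/render parameters. Mutant
#' ("mut") conditions use the mutant mode: fewer particles, a diffuse
#' cytoplasmic signal fraction, and increased lateral motion, emulating the
#' qualitative difference reported for mutant photoreceptors.
#'
#' @param condition one of [study_conditions()].
#' @param seed integer seed for the motion model.
#' @return list with elements `motion` ([motion_config()]) and `render`
#'   ([render_config()]).
#' @export
condition_presets <- function(condition, seed = 1L) {
  mutant <- grepl("^mut", condition)
  motion <- if (mutant) {
    motion_config(n_particles = 3L, sigma_lateral = 300, seed = seed)
  } else {
    motion_config(seed = seed)
  }
  render <- render_config(diffuse_fraction = if (mutant) 0.3 else 0,
                          seed = seed + 1L)
  list(motion = motion, render = render)
}

#' Simulate one photoreceptor recording
#'
#' Builds a geometry, simulates ground-truth trajectories and renders the
#' two-channel video for one cell of the given condition.
#'
#' @param condition one of [study_conditions()].
#' @param seed integer seed (drives geometry angle, motion and noise).
#' @param n_frames frames to simulate (default 600 = 10 min at 1 frame/s).
#' @param cell_length,cell_width cell footprint, px.
#' @param cell_id,animal_id identifiers carried into the outputs.
#' @return list with `stack`, `truth`, `geometry`, `condition`, `cell_id`,
#'   `animal_id`.
#' @export
simulate_pr <- function(condition = "wt Rab8a rods", seed = 1L,
                        n_frames = 600L, cell_length = 60, cell_width = 12,
                        cell_id = "cell_1", animal_id = "animal_1") {
  set.seed(seed)
  theta <- stats::runif(1, -pi / 3, pi / 3)
  geom <- make_geometry(theta, cell_length, cell_width, cell_id = cell_id,
                        seed = seed)
  preset <- condition_presets(condition, seed = seed + 1L)
  truth <- simulate_tracks(preset$motion, geom, n_frames)
  stack <- render_video(truth, geom, preset$render, n_frames = n_frames)
  list(stack = stack, truth = truth, geometry = geom, condition = condition,
       cell_id = cell_id, animal_id = animal_id)
}

#' Run the analysis stages on one recording
#'
#' register -> segment -> link -> filter -> per-track metrics -> per-cell
#' summary, with the configured parameters.
#'
#' @param stack a [frame_stack()].
#' @param geometry the cell's [make_geometry()] geometry.
#' @param seg a [segmentation_config()].
#' @param costs an [assignment_costs()].
#' @param contact a [contact_config()].
#' @param min_frames track eligibility threshold (>= 10 frames by default).
#' @param register apply translation registration first.
#' @param cell_id,condition,animal_id labels for the summary row.
#' @return list with `shifts`, `detections`, `tracks` (all linked),
#'   `eligible` (filtered tracks), `metrics` (per eligible track) and
#'   `summary` (one row).
#' @export
process_stack <- function(stack, geometry,
                          seg = segmentation_config(pixel_size_nm = stack$pixel_size_nm),
                          costs = assignment_costs(),
                          contact = contact_config(pixel_size_nm = stack$pixel_size_nm),
                          min_frames = 10L, register = TRUE,
                          cell_id = geometry$cell_id, condition = "wt",
                          animal_id = "animal_1") {
  shifts <- NULL
  if (register) {
    reg <- register_stack(stack)
    stack <- reg$stack
    shifts <- reg$shifts
  }
  detections <- segment_stack(stack, seg)
  tracks <- link_tracks(detections, costs, n_frames = n_frames(stack))
  eligible <- filter_tracks(tracks, min_frames)
  metrics <- track_metrics(eligible, geometry,
                           frame_interval_s = stack$frame_interval_s,
                           pixel_size_nm = stack$pixel_size_nm,
                           contact = contact)
  summary <- summarize_pr(metrics, cell_id = cell_id, condition = condition,
                          animal_id = animal_id)
  list(shifts = shifts, detections = detections, tracks = tracks,
       eligible = eligible, metrics = metrics, summary = summary)
}

#' Simulate and analyze a full study
#'
#' Replicates the study design: `n_per_condition` photoreceptors per
#' condition (13 by default), drawn from animals contributing 3-4 cells
#' each, every cell simulated, rendered and pushed through the complete
#' pipeline.
#'
#' @param conditions condition labels (default [study_conditions()]).
#' @param n_per_condition photoreceptors per condition.
#' @param n_frames frames per video (default 600).
#' @param seed master seed; every cell derives its own sub-seed.
#' @param register run translation registration (no drift is simulated by
#'   default, so this mostly verifies idempotence; disable to save time).
#' @param ... passed to [simulate_pr()] (e.g. `cell_length`).
#' @return list with `summaries` (one row per photoreceptor) and `metrics`
#'   (per-track metrics, with cell and condition labels).
#' @export
simulate_study <- function(conditions = study_conditions(),
                           n_per_condition = 13L, n_frames = 600L,
                           seed = 1L, register = FALSE, ...) {
  summaries <- list()
  all_metrics <- list()
  # animals contribute 3-4 cells each
  cells_per_animal <- rep(c(3L, 4L), length.out = 26L)
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    animal <- 1L
    left <- cells_per_animal[animal]
    for (pr in seq_len(n_per_condition)) {
      if (left == 0L) {
        animal <- animal + 1L
        left <- cells_per_animal[animal]
      }
      left <- left - 1L
      cell_seed <- as.integer((as.numeric(seed) * 1000 + ci * 100 + pr) %%
                                2147483647)
      sim <- simulate_pr(cond, seed = cell_seed, n_frames = n_frames,
                         cell_id = sprintf("%s_pr%02d", gsub(" ", "_", cond), pr),
                         animal_id = sprintf("%s_animal%d", gsub(" ", "_", cond), animal),
                         ...)
      res <- process_stack(sim$stack, sim$geometry, register = register,
                           cell_id = sim$cell_id, condition = cond,
                           animal_id = sim$animal_id)
      summaries[[length(summaries) + 1L]] <- res$summary
      if (nrow(res$metrics)) {
        m <- res$metrics
        m$cell_id <- sim$cell_id
        m$condition <- cond
        all_metrics[[length(all_metrics) + 1L]] <- m
      }
    }
  }
  list(summaries = do.call(rbind, summaries),
       metrics = do.call(rbind, all_metrics))
}

#' Pairwise and multi-group comparisons of a study table
#'
#' Reproduces the statistical protocol: equal-variance Student's t-tests for
#' pairwise wild-type vs mutant comparisons of kinetic parameters,
#' Mann-Whitney U for the (non-normal) contact parameters, and one-way
#' ANOVA across the three wild-type groups for each kinetic parameter.
#'
#' @param summaries per-photoreceptor summary table from [simulate_study()]
#'   or built from [summarize_pr()] rows.
#' @return data.frame: `metric`, `comparison`, `test`, `statistic`, `p`,
#'   `stars` (`*` p < 0.05, `**` p < 0.01).
#' @export
study_comparisons <- function(summaries) {
  kin <- c("displacement_nm", "trajectory_um", "max_speed_nm_s",
           "directionality", "area_um2")
  contacts <- c("contact_proportion", "n_contacting")
  get <- function(cond, metric) {
    summaries[summaries$condition == cond, metric]
  }
  rows <- list()
  add <- function(metric, comparison, cr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, comparison = comparison, test = cr$test_name,
      statistic = cr$statistic, p = cr$p_value,
      stars = if (cr$p_value < 0.01) "**" else if (cr$p_value < 0.05) "*" else "ns")
  }
  pairs <- list(c("wt Rab8a rods", "mut Rab8a rods"),
                c("wt Rab8ba rods", "mut Rab8ba rods"))
  conds <- unique(summaries$condition)
  for (pr in pairs) {
    if (!all(pr %in% conds)) next
    for (metric in kin) {
      a <- get(pr[1], metric); b <- get(pr[2], metric)
      if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
        add(metric, paste(pr, collapse = " vs "),
            compare_two(a, b, "student_t"))
      }
    }
    for (metric in contacts) {
      a <- get(pr[1], metric); b <- get(pr[2], metric)
      if (sum(!is.na(a)) >= 1 && sum(!is.na(b)) >= 1) {
        add(metric, paste(pr, collapse = " vs "),
            compare_two(a, b, "mann_whitney_u"))
      }
    }
  }
  wt <- c("wt Rab8a cones", "wt Rab8a rods", "wt Rab8ba rods")
  if (all(wt %in% conds)) {
    for (metric in kin) {
      gs <- lapply(wt, get, metric = metric)
      names(gs) <- wt
      gs <- lapply(gs, function(g) g[!is.na(g)])
      if (all(vapply(gs, length, integer(1)) >= 2)) {
        add(metric, "wt groups", compare_many(gs))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
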