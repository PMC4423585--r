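#' Study configuration
#'
#' Bundles every tunable of the two-phase protocol study into one object.
#' Defaults reproduce the reference protocol: 11 subjects per group,
#' sampling periods 2..40 slices, 5000 randomized repetitions per period,
#' ICC threshold 0.99 at 95% confidence, spread threshold 0.005, three
#' simulated automated tools and three manual tracings (operator 1 in both
#' phases, operator 2 in phase 1).
#'
#' @param master_seed integer master seed (mandatory); every stage derives
#'   its own stream from it.
#' @param n_subjects subjects per group (default 11).
#' @param groups group labels to simulate (default AD and AC).
#' @param periods sampling periods in slices (default `2:40`).
#' @param n_reps randomized repetitions per period (default 5000).
#' @param icc_threshold,confidence,spread_max guideline thresholds (see
#'   [guideline_max_period()]).
#' @param grid_shape,spacing phantom voxel grid (default 192^3 at 1 mm
#'   isotropic; the slice spacing is `spacing[3]`).
#' @param operator_jitter_sd boundary jitter SD in mm shared by the three
#'   tracings (default 0.02 mm, calibrated so tracing MRPAD sits at the
#'   0.002-0.014% scale of careful manual raters).
#' @param tools list of [tool_model()]s (default the three presets).
#' @param glm_formula formula for the factorial GLM stage (default the full
#'   four-way factorial `icv_l ~ group * sex * age * method`; reduce it for
#'   small cohorts, where the full design is rank-deficient).
#' @param out_dir optional output directory; when set, [run_study()] writes
#'   all stage artifacts there.
#' @param write_masks write phantom/traced masks as NIfTI under `out_dir`
#'   (default FALSE; masks are large).
#' @return an object of class `study_config`.
#' @export
study_config <- function(master_seed,
                         n_subjects = 11L,
                         groups = c("AD", "AC"),
                         periods = 2:40,
                         n_reps = 5000L,
                         icc_threshold = 0.99,
                         confidence = 0.95,
                         spread_max = 0.005,
                         grid_shape = c(192L, 192L, 192L),
                         spacing = c(1, 1, 1),
                         operator_jitter_sd = 0.02,
                         tools = NULL,
                         glm_formula = icv_l ~ group * sex * age * method,
                         out_dir = NULL,
                         write_masks = FALSE) {
  if (missing(master_seed) || !is.numeric(master_seed))
    stop_icv("`master_seed` is mandatory", "icv_input_error")
  if (is.null(tools))
    tools <- list(tool_preset("FS"), tool_preset("FSL"), tool_preset("SPM"))
  if (!all(vapply(tools, inherits, logical(1), "tool_model")))
    stop_icv("`tools` must be a list of tool_model objects", "icv_input_error")
  if (icc_threshold <= 0 || icc_threshold > 1 || spread_max < 0 ||
      confidence <= 0 || confidence >= 1)
    stop_icv("guideline thresholds out of range", "icv_input_error")
  structure(
    list(master_seed = as.integer(master_seed),
         n_subjects = as.integer(n_subjects),
         groups = as.character(groups),
         periods = as.integer(periods), n_reps = as.integer(n_reps),
         icc_threshold = icc_threshold, confidence = confidence,
         spread_max = spread_max,
         grid_shape = as.integer(grid_shape), spacing = as.double(spacing),
         operator_jitter_sd = as.double(operator_jitter_sd),
         tools = tools, glm_formula = glm_formula, out_dir = out_dir,
         write_masks = isTRUE(write_masks)),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#'
#' Accepts the [study_config()] argument names as top-level YAML keys;
#' tools are given as a list of `{name, mult_bias, noise_cv}` maps.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [study_config()].
#' @return a `study_config`.
#' @export
read_study_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$tools))
    raw$tools <- lapply(raw$tools, function(t)
      tool_model(t$name, t$mult_bias, t$noise_cv))
  if (!is.null(raw$glm_formula))
    raw$glm_formula <- as.formula(raw$glm_formula)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(study_config, raw)
}

#' Run the full protocol-evaluation study
#'
#' Executes the two-phase study on synthetic cohorts, entirely determined
#' by the configuration and its master seed:
#'
#' 1. per group, generate a phantom cohort ([generate_cohort()]);
#' 2. simulate the three manual tracings (operator 1 phases I and II,
#'    operator 2 phase I) of every subject and take operator 1 / phase I
#'    as the reference measurement;
#' 3. simulate each automated tool in both phases
#'    ([simulate_tool_icv()]);
#' 4. run the randomized subsampling reliability analysis on the reference
#'    tracings ([run_randomized_reliability()]) and extract both guideline
#'    criteria ([guideline_max_period()]);
#' 5. compute the agreement batteries (operators, tools vs reference,
#'    phase consistency) and the factorial GLM.
#'
#' @param config a [study_config()].
#' @return an object of class `study_report`: list with `per_group`
#'   (reliability curve, guidelines, comparison tables per group),
#'   `icv_table`, `anova`, and a `provenance` block. When
#'   `config$out_dir` is set the report and stage tables are also written
#'   there (`report.json`, `icv_table.csv`, `reliability_curve_<G>.csv`,
#'   `icc_draws_<G>.csv`, `guidelines.json`, `anova.csv`).
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config"))
    stop_icv("`config` must be a study_config", "icv_input_error")
  slice_dz <- config$spacing[3]
  ops <- list(
    manual_op1 = list(op = operator_model(config$operator_jitter_sd,
                                          seed_offset = 1L,
                                          name = "manual_op1"), phase = 1L),
    manual_op2 = list(op = operator_model(config$operator_jitter_sd,
                                          seed_offset = 2L,
                                          name = "manual_op2"), phase = 1L),
    manual_op1_p2 = list(op = operator_model(config$operator_jitter_sd,
                                             seed_offset = 3L,
                                             name = "manual_op1"),
                         phase = 2L))
  per_group <- list()
  icv_rows <- list()
  for (g in config$groups) {
    stage <- sprintf("group %s", g)
    gseed <- derive_seed(config$master_seed, match(g, config$groups))
    res <- tryCatch(
      run_group_stage(config, g, gseed, ops, slice_dz),
      error = function(e) stop_icv(
        sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        "icv_stage_error"))
    per_group[[g]] <- res$group_result
    icv_rows[[g]] <- res$icv_rows
  }
  tab <- validate_icv_table(do.call(rbind, unname(icv_rows)))
  # Table-3-style factorial GLM on phase-I measurements (manual reference
  # plus the simulated tools).
  glm_tab <- tab[tab$phase == 1L & tab$method != "manual_op2", , drop = FALSE]
  glm_tab$method[glm_tab$method == "manual_op1"] <- "manual"
  anova <- factorial_glm_anova(glm_tab, formula = config$glm_formula)
  report <- structure(
    list(per_group = per_group, icv_table = tab, anova = anova,
         provenance = list(master_seed = config$master_seed,
                           n_subjects = config$n_subjects,
                           groups = config$groups,
                           periods = range(config$periods),
                           n_reps = config$n_reps,
                           spacing = config$spacing,
                           package_version =
                             as.character(utils::packageVersion("icvsampler")))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config)
  report
}

run_group_stage <- function(config, g, gseed, ops, slice_dz) {
  spec <- phantom_preset(g, grid_shape = config$grid_shape,
                         spacing = config$spacing)
  # Stream subjects: generate, trace, reduce to profiles, drop the voxels.
  cohort <- generate_cohort(spec, config$n_subjects, g, gseed,
                            keep_masks = TRUE)
  n <- nrow(cohort$subjects)
  traced_icv <- matrix(NA_real_, n, length(ops),
                       dimnames = list(NULL, names(ops)))
  ref_profiles <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- cohort$masks[[i]]
    sseed <- cohort$subjects$seed[i]
    for (k in seq_along(ops)) {
      traced <- simulate_operator_tracing(mask, ops[[k]]$op,
                                          derive_seed(sseed, k, stream = 3L))
      traced_icv[i, k] <- icv_from_mask(traced)
      if (names(ops)[k] == "manual_op1")
        ref_profiles[[i]] <- structure(
          list(counts = slice_counts(traced), spacing = traced$spacing),
          class = "slice_profile")
    }
    if (config$write_masks && !is.null(config$out_dir)) {
      dir.create(file.path(config$out_dir, "masks"), showWarnings = FALSE,
                 recursive = TRUE)
      write_mask_nifti(mask, file.path(
        config$out_dir, "masks",
        paste0(cohort$subjects$subject_id[i], ".nii.gz")))
    }
    cohort$masks[i] <- list(NULL)  # free the voxel data
  }
  ref_icv <- traced_icv[, "manual_op1"]

  tool_icv <- list()
  for (t in seq_along(config$tools)) {
    tool <- config$tools[[t]]
    for (ph in 1:2)
      tool_icv[[paste0(tolower(tool$name), "_p", ph)]] <-
        simulate_tool_icv(cohort$subjects$true_icv_l, tool,
                          seed = derive_seed(gseed, t, stream = 10L + ph))
  }

  draws <- run_randomized_reliability(ref_profiles,
                                      reference_icvs = ref_icv,
                                      periods = config$periods,
                                      n_reps = config$n_reps,
                                      seed = derive_seed(gseed, 0L,
                                                         stream = 20L))
  curve <- summarize_curve(draws)
  guidelines <- list(
    confidence_icc = guideline_max_period(
      curve, "confidence_icc", icc_threshold = config$icc_threshold,
      confidence = config$confidence, slice_spacing = slice_dz),
    tight_spread = guideline_max_period(
      curve, "tight_spread", spread_max = config$spread_max,
      slice_spacing = slice_dz))

  subj <- cohort$subjects
  mk_rows <- function(method, phase, icv)
    data.frame(subject_id = subj$subject_id, group = g, sex = subj$sex,
               age = subj$age, method = method, phase = phase, icv_l = icv,
               stringsAsFactors = FALSE)
  icv_rows <- rbind(
    mk_rows("manual_op1", 1L, traced_icv[, "manual_op1"]),
    mk_rows("manual_op2", 1L, traced_icv[, "manual_op2"]),
    mk_rows("manual_op1", 2L, traced_icv[, "manual_op1_p2"]),
    do.call(rbind, lapply(names(tool_icv), function(nm) {
      method <- sub("_p[12]$", "", nm)
      phase <- as.integer(sub("^.*_p", "", nm))
      mk_rows(method, phase, tool_icv[[nm]])
    })))

  operator_agreement <- rbind(
    pair_comparison_row(
      data.frame(subject_id = subj$subject_id,
                 icv_l = traced_icv[, "manual_op1"]),
      data.frame(subject_id = subj$subject_id,
                 icv_l = traced_icv[, "manual_op1_p2"]),
      label_a = "manual_op1@phase1", label_b = "manual_op1@phase2",
      group = g),
    pair_comparison_row(
      data.frame(subject_id = subj$subject_id,
                 icv_l = traced_icv[, "manual_op1"]),
      data.frame(subject_id = subj$subject_id,
                 icv_l = traced_icv[, "manual_op2"]),
      label_a = "manual_op1@phase1", label_b = "manual_op2@phase1",
      group = g))
  tool_vs_reference <- comparison_battery(
    validate_icv_table(icv_rows), reference_method = "manual_op1",
    group = g, phase = 1L,
    methods = setdiff(unique(icv_rows$method),
                      c("manual_op1", "manual_op2")))
  phase_consistency <- phase_consistency_battery(
    validate_icv_table(icv_rows), group = g)

  list(group_result = list(
         subjects = subj,
         reliability_curve = curve,
         icc_draws = draws,
         guidelines = guidelines,
         operator_agreement = operator_agreement,
         tool_vs_reference = tool_vs_reference,
         phase_consistency = phase_consistency,
         reference_icv = ref_icv),
       icv_rows = icv_rows)
}

write_study_report <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  write_icv_table(report$icv_table, out("icv_table.csv"))
  write.csv(report$anova, out("anova.csv"), row.names = FALSE)
  guide <- list()
  for (g in names(report$per_group)) {
    pg <- report$per_group[[g]]
    write.csv(pg$reliability_curve, out(sprintf("reliability_curve_%s.csv", g)),
              row.names = FALSE)
    write.csv(pg$icc_draws, out(sprintf("icc_draws_%s.csv", g)),
              row.names = FALSE)
    guide[[g]] <- lapply(pg$guidelines, unclass)
  }
  jsonlite::write_json(guide, out("guidelines.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  json_report <- list(
    provenance = report$provenance,
    anova = report$anova,
    per_group = lapply(report$per_group, function(pg)
      list(reliability_curve = pg$reliability_curve,
           guidelines = lapply(pg$guidelines, unclass),
           operator_agreement = pg$operator_agreement,
           tool_vs_reference = pg$tool_vs_reference,
           phase_consistency = pg$phase_consistency)))
  jsonlite::write_json(json_report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(config$out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (g in names(x$per_group)) {
    gl <- x$per_group[[g]]$guidelines
    cat(sprintf("  %s: confidence_icc max period %s slices (%s mm); tight_spread %s slices\n",
                g,
                format(gl$confidence_icc$max_period_slices),
                format(gl$confidence_icc$max_period_mm),
                format(gl$tight_spread$max_period_slices)))
  }
  cat(sprintf("  seed %d, %d reps/period\n", x$provenance$master_seed,
              x$provenance$n_reps))
  invisible(x)
}

#' Write small deterministic test fixtures
#'
#' Produces the fixture bundle used by the worked examples: a 10-slice
#' constant-area profile mask (100 mm^2 per slice), an empty mask, a small
#' smooth phantom, the 3-subject paired ICC table with known ICC 2/3, and
#' a JSON file of the corresponding expected values.
#'
#' @param seed integer seed for the phantom fixture.
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("icv_fixtures_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  occ <- array(0L, c(16L, 16L, 20L))
  occ[4:13, 4:13, 6:15] <- 1L  # 10 x 10 mm^2 cross-section, slices 6..15
  profile_mask <- mask_volume(occ, spacing = c(1, 1, 1))
  paths$profile_mask <- file.path(dir, "constant_profile_mask.nii.gz")
  write_mask_nifti(profile_mask, paths$profile_mask)

  paths$empty_mask <- file.path(dir, "empty_mask.nii.gz")
  write_mask_nifti(mask_volume(array(0L, c(8L, 8L, 8L)), c(1, 1, 1)),
                   paths$empty_mask)

  spec <- phantom_spec(c(30, 25, 20), grid_shape = c(72L, 72L, 72L))
  paths$phantom <- file.path(dir, "smooth_phantom.nii.gz")
  write_mask_nifti(generate_phantom(spec, subject_seed = seed),
                   paths$phantom)

  icc_tab <- data.frame(x = c(1, 2, 3), y = c(2, 3, 4))
  paths$icc_table <- file.path(dir, "icc_pairs.csv")
  write.csv(icc_tab, paths$icc_table, row.names = FALSE)

  expected <- list(
    profile_mask = list(icv_l = 0.001,
                        subsample_m3_start0_icv_l = 0.0012),
    phantom = list(analytic_volume_l = ellipsoid_volume_l(c(30, 25, 20))),
    icc_table = list(icc = 2 / 3))
  paths$expected <- file.path(dir, "expected.json")
  jsonlite::write_json(expected, paths$expected, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
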