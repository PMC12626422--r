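# End-to-end orchestration: simulate (or load) -> events -> connectivity /
# maturity -> ISS -> group statistics, with a machine-readable report.

.pipeline_keys <- c("version", "seed", "simulate", "input_dir", "atlas",
                    "alpha", "min_len_tr", "maturity_scale",
                    "maturity_average", "iss_method", "age_groups",
                    "out_dir")

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are errors (protection against silently misspelled
#' thresholds). Either a `simulate` block (arguments for [synth_config()],
#' seed excluded) or an `input_dir` fixture directory must be given.
#'
#' @param config a named list, or the path of a YAML file holding one.
#' @return the completed configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .pipeline_keys)
  .check(length(unknown) == 0, "unknown config key(s): %s",
         paste(unknown, collapse = ", "))
  defaults <- list(version = 1, atlas = "default", alpha = 0.05,
                   min_len_tr = 2, maturity_scale = "z",
                   maturity_average = "r", iss_method = "average_series",
                   age_groups = "tertile", out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  .check(!is.null(config$simulate) || !is.null(config$input_dir),
         "config needs either a 'simulate' block or an 'input_dir'")
  .check(!is.null(config$seed), "config needs a 'seed'")
  config
}

#' Run the full dyadic analysis pipeline
#'
#' Stages, in order: obtain data (synthetic cohort or fixture directory);
#' reverse-correlation event detection on the adult network timecourses and
#' the ToM/SP-vs-other mask; per-subject connectivity matrices, block means
#' and neural maturity (whole-run and event-restricted); child-mother and
#' child-stranger ISS (whole-run and event-restricted); and the group
#' statistics layer with per-family FDR. All artifacts are written under
#' `out_dir` when given, together with a manifest; the report is a pure
#' function of (inputs, config, seed).
#'
#' @param config configuration list or YAML path (see [pipeline_config()]).
#' @return the report: a named list of tables and summaries; attribute
#'   `"report_md5"` carries the hash of the serialized report when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  atlas <- if (identical(cfg$atlas, "default")) load_default_atlas()
           else read_atlas(cfg$atlas)

  ds <- if (!is.null(cfg$simulate)) {
    generate_dyads(do.call(synth_config, c(cfg$simulate, list(seed = cfg$seed))))
  } else {
    read_fixture(cfg$input_dir)
  }
  children <- ds$children
  mothers <- ds$mothers
  behavior <- ds$behavior
  tr_s <- children[[1]]$tr_seconds
  n_tr <- ncol(children[[1]]$data)

  # --- reverse correlation on adults --------------------------------------
  events <- list()
  for (net in c("ToM", "SPM")) {
    stack <- group_stack(mothers, which = net, atlas = atlas)
    tt <- per_tr_ttest(stack)
    ev <- detect_events(tt, alpha = cfg$alpha, min_len_tr = cfg$min_len_tr,
                        tr_seconds = tr_s)
    ev <- rank_and_label(ev, colMeans(stack$data),
                         prefix = if (net == "ToM") "T" else "P")
    ev$network <- if (nrow(ev)) net else character(0)
    events[[net]] <- ev
  }
  mask <- build_event_mask(events$ToM, events$SPM, n_tr, tr_s)
  event_summary <- list(ToM = summarize_events(events$ToM, tr_s),
                        SPM = summarize_events(events$SPM, tr_s))

  # replication of the adult events in the child group
  child_repl <- lapply(c(ToM = "ToM", SPM = "SPM"), function(net)
    child_event_replication(group_stack(children, which = net, atlas = atlas),
                            events[[net]], alpha = cfg$alpha,
                            min_len_tr = cfg$min_len_tr))

  # --- connectivity and neural maturity -----------------------------------
  child_cm <- lapply(children, interregion_matrix)
  adult_cm <- lapply(mothers, interregion_matrix)
  blocks <- list(
    adult = block_means(group_mean_matrix(adult_cm), atlas),
    child = block_means(group_mean_matrix(child_cm), atlas)
  )
  maturity_all <- do.call(rbind, lapply(child_cm, function(cm) {
    ms <- neural_maturity(cm, adult_cm, scale = cfg$maturity_scale,
                          average = cfg$maturity_average)
    data.frame(subject_id = ms$subject_id, condition = "all",
               value = ms$value, n_adults = ms$n_adults,
               stringsAsFactors = FALSE)
  }))
  maturity_cond <- maturity_by_condition(children, mothers, mask)
  maturity <- rbind(maturity_all, maturity_cond)
  rownames(maturity) <- NULL
  behavior <- assign_age_groups(behavior, cfg$age_groups)

  # --- inter-subject synchronization --------------------------------------
  child_series <- lapply(children, network_mean_timecourse, which = "all",
                         atlas = atlas)
  adult_series <- lapply(mothers, network_mean_timecourse, which = "all",
                         atlas = atlas)
  mother_of <- stats::setNames(behavior$mother_id, behavior$child_id)
  iss <- iss_contrast_table(child_series, adult_series, mother_of,
                            mask = mask)

  # --- group statistics ----------------------------------------------------
  ord <- match(behavior$child_id, maturity_all$subject_id)
  mat_all <- maturity_all$value[ord]
  mat_tom <- maturity$value[maturity$condition == "tom_sp"][ord]
  mat_oth <- maturity$value[maturity$condition == "other"][ord]
  iss_row <- function(p, cond) {
    sub <- iss[iss$partner == p & iss$condition == cond, ]
    sub$z[match(behavior$child_id, sub$child_id)]
  }
  stats_tbl <- rbind(
    within(pearson_test(behavior$age, mat_all, "maturity_vs_age"),
           family_id <- "maturity"),
    within(pearson_test(behavior$age, mat_tom, "maturity_tom_sp_vs_age"),
           family_id <- "maturity"),
    within(pearson_test(behavior$age, mat_oth, "maturity_other_vs_age"),
           family_id <- "maturity"),
    within(pearson_test(behavior$conflict, mat_all, "maturity_vs_conflict"),
           family_id <- "maturity"),
    within(partial_correlation(behavior$conflict, iss_row("mother", "all"),
                               behavior$age, "conflict_vs_mother_iss"),
           family_id <- "iss"),
    within(partial_correlation(behavior$conflict, iss_row("stranger", "all"),
                               behavior$age, "conflict_vs_stranger_iss"),
           family_id <- "iss"),
    two_sample_t(iss_row("mother", "all"), iss_row("stranger", "all"),
                 name = "mother_vs_stranger_iss"),
    paired_t(iss_row("mother", "all"), iss_row("stranger", "all"),
             name = "mother_vs_stranger_iss_paired"),
    paired_t(mat_tom, mat_oth, name = "maturity_tom_sp_vs_other_paired")
  )
  stats_tbl <- adjust_families(stats_tbl)

  iss_anova <- anova_twoway(
    within(iss[iss$condition != "all", ], condition <- as.character(condition)),
    y = "z", factor_a = "partner", factor_b = "condition")
  mat_long <- merge(maturity_cond,
                    behavior[, c("child_id", "age_group")],
                    by.x = "subject_id", by.y = "child_id")
  maturity_anova <- anova_twoway(mat_long, y = "value",
                                 factor_a = "condition",
                                 factor_b = "age_group")

  # variable table for external latent-variable modeling
  sem_table <- data.frame(
    behavior[, c("child_id", "age", "sex", "conflict", "closeness",
                 "rejection", "warmth", "control", "ppvt", "tom_score",
                 "srs_total")],
    neural_maturity = mat_all,
    mother_iss_z = iss_row("mother", "all"),
    stringsAsFactors = FALSE
  )

  report <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    events = do.call(rbind, unname(events)),
    event_summary = event_summary,
    event_mask = list(n_tom_sp = mask$n_tom_sp, n_other = mask$n_other,
                      tom_sp_s = mask$tom_sp_s, other_s = mask$other_s,
                      overlap_trs = mask$overlap_trs),
    child_replication = lapply(child_repl, as.logical),
    block_means = blocks,
    maturity = maturity,
    age_groups = as.list(table(behavior$age_group)),
    iss = iss,
    stats = stats_tbl,
    iss_anova = iss_anova,
    maturity_anova = maturity_anova,
    sem_table = sem_table
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(report$events, file.path(cfg$out_dir, "events.tsv"))
    .write_tsv(data.frame(tr = seq_len(n_tr) - 1L,
                          condition = ifelse(mask$tom_sp, "tom_sp", "other")),
               file.path(cfg$out_dir, "event_mask.tsv"))
    .write_tsv(report$maturity, file.path(cfg$out_dir, "maturity.tsv"))
    .write_tsv(report$iss, file.path(cfg$out_dir, "iss.tsv"))
    .write_tsv(report$stats, file.path(cfg$out_dir, "stats.tsv"))
    .write_tsv(report$sem_table, file.path(cfg$out_dir, "sem_table.tsv"))
    report_path <- file.path(cfg$out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", force = TRUE)
    attr(report, "report_md5") <- unname(tools::md5sum(report_path))
  }
  report
}
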