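#' Run the mode-comparison experiment on a cohort
#'
#' Reproduces the framework's comparison design on a mediator library and a
#' set of test subjects: direct subject-to-template registration, a single
#' arbitrary fixed mediator, and multi-mediator registration with
#' criterion-based selection. Every subject's brain mask is carried into the
#' template space through the relevant composed transform and scored by Dice
#' against the template mask; a Dice above `threshold` counts as a
#' registration success.
#'
#' Subject-to-mediator registrations are computed once per (subject,
#' mediator) pair and shared across the `single` and `multi` modes and all
#' criteria, so adding criteria is free. Everything is deterministic given
#' the inputs.
#'
#' @param library a `medbridge_library` whose entries carry masks.
#' @param subjects list of `medbridge_phantom_sample`s (or any objects with
#'   `$volume`, `$brain_mask` and optionally `$id`).
#' @param modes subset of `c("direct", "single", "multi")`.
#' @param criteria subset of `c("ssd", "mi", "oracle_dice")` (multi mode).
#' @param cfg a [registration_config()].
#' @param threshold Dice success threshold (default 0.85).
#' @param single_mediator_id mediator used in `single` mode; default the
#'   library's first entry.
#' @return A list of class `medbridge_experiment`: `per_subject`
#'   (data.frame: subject_id, mode, criterion, mediator_id, dice),
#'   `summary` (per mode/criterion mean dice and success rate), `threshold`,
#'   `selections` (per-subject `medbridge_selection`s when computed).
#' @export
run_experiment <- function(library, subjects,
                           modes = c("direct", "single", "multi"),
                           criteria = c("ssd", "mi", "oracle_dice"),
                           cfg = registration_config(),
                           threshold = 0.85,
                           single_mediator_id = NULL) {
  stopifnot(inherits(library, "medbridge_library"))
  if (length(subjects) == 0L) stop("empty subject list")
  modes <- match.arg(modes, several.ok = TRUE)
  criteria <- match.arg(criteria, several.ok = TRUE)
  ids <- library_ids(library)
  if (is.null(single_mediator_id)) single_mediator_id <- ids[1]
  if (!single_mediator_id %in% ids)
    stop("unknown single mediator id: ", single_mediator_id)
  subj_ids <- vapply(seq_along(subjects), function(j) {
    s <- subjects[[j]]
    if (!is.null(s$id)) s$id else sprintf("sub%02d", j)
  }, character(1))
  for (s in subjects)
    if (is.null(s$brain_mask)) stop("subjects must carry brain masks")

  rows <- list()
  selections <- list()
  add_row <- function(subject_id, mode, criterion, mediator_id, dice_val)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject_id, mode = mode, criterion = criterion,
      mediator_id = mediator_id, dice = dice_val, stringsAsFactors = FALSE)

  need_candidates <- any(c("single", "multi") %in% modes)
  for (j in seq_along(subjects)) {
    s <- subjects[[j]]
    if ("direct" %in% modes) {
      cand <- register_direct(s$volume, library, cfg)
      mask_t <- apply_to_template(s$brain_mask, cand$composed, library)
      add_row(subj_ids[j], "direct", "none", "__direct__",
              dice(mask_t, library$template_mask))
    }
    if (need_candidates) {
      candidates <- lapply(library$entries, function(e)
        score_candidate(s$volume, e, library, cfg,
                        subject_mask = s$brain_mask))
      names(candidates) <- ids
      if ("single" %in% modes)
        add_row(subj_ids[j], "single", "none", single_mediator_id,
                candidates[[single_mediator_id]]$dice_oracle)
      if ("multi" %in% modes) {
        for (crit in criteria) {
          sel <- select_candidate(candidates, crit)
          add_row(subj_ids[j], "multi", crit, sel$chosen_id,
                  sel$candidates[[which(ids == sel$chosen_id)]]$dice_oracle)
          selections[[paste(subj_ids[j], crit, sep = ":")]] <- sel
        }
      }
    }
  }
  per_subject <- do.call(rbind, rows)
  structure(list(per_subject = per_subject,
                 summary = experiment_summary_table(per_subject, threshold),
                 threshold = threshold, selections = selections),
            class = "medbridge_experiment")
}

experiment_summary_table <- function(per_subject, threshold) {
  key <- interaction(per_subject$mode, per_subject$criterion, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    d <- per_subject[key == k, ]
    data.frame(mode = d$mode[1], criterion = d$criterion[1],
               n = nrow(d), mean_dice = mean(d$dice),
               min_dice = min(d$dice), max_dice = max(d$dice),
               success_rate = mean(d$dice > threshold),
               stringsAsFactors = FALSE)
  }))
  out[order(out$mode, out$criterion), , drop = FALSE]
}

#' @export
print.medbridge_experiment <- function(x, ...) {
  cat(sprintf("<experiment> %d subject-rows, success threshold %.2f\n",
              nrow(x$per_subject), x$threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Summarize an experiment report
#'
#' Per-mode/criterion mean, min, max Dice and success rate, plus binned Dice
#' histogram counts with cumulative percentages (0.05-wide bins over [0, 1]).
#'
#' @param report a `medbridge_experiment`.
#' @param bin_width Dice histogram bin width.
#' @return A list with `summary` and `histogram` data.frames.
#' @export
summarize_experiment <- function(report, bin_width = 0.05) {
  stopifnot(inherits(report, "medbridge_experiment"))
  ps <- report$per_subject
  if (nrow(ps) == 0L) stop("empty report")
  breaks <- seq(0, 1, by = bin_width)
  key <- interaction(ps$mode, ps$criterion, drop = TRUE)
  hist_df <- do.call(rbind, lapply(levels(key), function(k) {
    d <- ps[key == k, ]
    counts <- as.integer(table(cut(d$dice, breaks,
                                   include.lowest = TRUE, right = TRUE)))
    data.frame(mode = d$mode[1], criterion = d$criterion[1],
               bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
               count = counts,
               cumulative_pct = 100 * cumsum(counts) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  list(summary = report$summary, histogram = hist_df)
}

#' Write an experiment report to CSV files
#'
#' Writes `per_subject.csv`, `summary.csv` and `histogram.csv` under `dir`.
#'
#' @param report a `medbridge_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(report, dir) {
  stopifnot(inherits(report, "medbridge_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- summarize_experiment(report)
  write.csv(report$per_subject, file.path(dir, "per_subject.csv"),
            row.names = FALSE)
  write.csv(sm$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(sm$histogram, file.path(dir, "histogram.csv"), row.names = FALSE)
  invisible(dir)
}
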