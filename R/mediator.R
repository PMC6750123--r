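#' Direct registration of a subject to the library template
#'
#' The conventional baseline: one affine registration straight from the
#' subject to the template, no mediator. Returned as a candidate record with
#' `mediator_id = "__direct__"` whose composed transform is the registration
#' output itself.
#'
#' @param subject subject `medbridge_volume`.
#' @param library a `medbridge_library`.
#' @param cfg a [registration_config()].
#' @return A list of class `medbridge_candidate` with elements `mediator_id`,
#'   `subject_to_mediator`, `composed`, `converged`.
#' @export
register_direct <- function(subject, library, cfg = registration_config()) {
  stopifnot(inherits(library, "medbridge_library"))
  reg <- register_affine(subject, library$template, cfg,
                         from_space = "subject",
                         to_space = library$space_label)
  structure(list(mediator_id = "__direct__",
                 subject_to_mediator = reg$transform,
                 ssd = NA_real_, mi = NA_real_, dice_oracle = NA_real_,
                 composed = reg$transform,
                 converged = reg$converged),
            class = "medbridge_candidate")
}

# score one mediator: register subject to it, compute criteria on the
# mediator's grid, compose into template space
score_candidate <- function(subject, entry, library, cfg,
                            subject_mask = NULL, mi_bins = 64L,
                            match_levels = 256L) {
  reg <- register_affine(subject, entry$volume, cfg,
                         from_space = "subject", to_space = entry$id)
  t_sm <- reg$transform
  subj_on_med <- resample(subject, entry$volume, t_sm)
  med_matched <- histogram_match(entry$volume, subj_on_med, match_levels)
  ssd_val <- ssd(med_matched, subj_on_med)
  mi_val <- mutual_information(entry$volume, subj_on_med, mi_bins)
  composed <- compose_affine(t_sm, entry$to_template)
  dice_val <- NA_real_
  if (!is.null(subject_mask)) {
    mask_t <- resample(subject_mask, library$template, composed,
                       interpolation = "nearest")
    dice_val <- dice(mask_t, library$template_mask)
  }
  structure(list(mediator_id = entry$id,
                 subject_to_mediator = t_sm,
                 ssd = ssd_val, mi = mi_val, dice_oracle = dice_val,
                 composed = composed, converged = reg$converged),
            class = "medbridge_candidate")
}

#' Multi-mediator registration with criterion-based selection
#'
#' Registers the subject to every mediator in the library, scores each
#' candidate, selects the best one under the requested criterion, and
#' composes the winner's subject-to-mediator transform with the mediator's
#' pre-determined transform into the template space. Criteria:
#' \describe{
#'   \item{`ssd`}{smallest sum of squared differences between each mediator
#'     (histogram-matched to the registered subject) and the subject
#'     resampled onto that mediator's grid.}
#'   \item{`mi`}{highest mutual information between mediator and registered
#'     subject (no intensity matching).}
#'   \item{`oracle_dice`}{highest Dice of the subject brain mask, carried
#'     through each composed transform, against the template mask — the
#'     "true best" mediator, available only when masks exist.}
#' }
#' SSD and MI are always recorded for every candidate; the oracle Dice is
#' recorded whenever `subject_mask` is given. Ties break in library order.
#'
#' @param subject subject `medbridge_volume`.
#' @param library a non-empty `medbridge_library`.
#' @param criterion one of `"ssd"`, `"mi"`, `"oracle_dice"`.
#' @param cfg a [registration_config()].
#' @param subject_mask subject brain `medbridge_mask`; required for
#'   `criterion = "oracle_dice"`.
#' @param mi_bins,match_levels similarity settings (see
#'   [mutual_information()], [histogram_match()]).
#' @return A list of class `medbridge_selection`: `candidates` (one per
#'   mediator, library order), `criterion`, `chosen_id`, `chosen_transform`
#'   (subject -> template).
#' @export
run_multi_mediator <- function(subject, library,
                               criterion = c("ssd", "mi", "oracle_dice"),
                               cfg = registration_config(),
                               subject_mask = NULL,
                               mi_bins = 64L, match_levels = 256L) {
  stopifnot(inherits(library, "medbridge_library"))
  criterion <- match.arg(criterion)
  if (length(library$entries) == 0L) stop("empty mediator library")
  if (criterion == "oracle_dice" && is.null(subject_mask))
    stop("criterion 'oracle_dice' requires a subject mask")
  candidates <- lapply(library$entries, function(e)
    score_candidate(subject, e, library, cfg, subject_mask = subject_mask,
                    mi_bins = mi_bins, match_levels = match_levels))
  select_candidate(candidates, criterion)
}

# pick the optimum under a criterion; first (library-order) winner on ties
select_candidate <- function(candidates, criterion) {
  scores <- switch(criterion,
    ssd = vapply(candidates, function(cd) cd$ssd, numeric(1)),
    mi = vapply(candidates, function(cd) cd$mi, numeric(1)),
    oracle_dice = vapply(candidates, function(cd) cd$dice_oracle, numeric(1)))
  if (any(is.na(scores)))
    stop("criterion '", criterion, "' not available for all candidates")
  best <- if (criterion == "ssd") which.min(scores) else which.max(scores)
  chosen <- candidates[[best]]
  structure(list(candidates = candidates, criterion = criterion,
                 chosen_id = chosen$mediator_id,
                 chosen_transform = chosen$composed),
            class = "medbridge_selection")
}

#' @export
print.medbridge_selection <- function(x, ...) {
  cat(sprintf("<mediator selection> criterion %s, chose '%s' of %d candidates\n",
              x$criterion, x$chosen_id, length(x$candidates)))
  invisible(x)
}

#' Candidate scores as a data frame
#'
#' @param x a `medbridge_selection`.
#' @param ... unused.
#' @return data.frame with one row per candidate: `mediator_id`, `ssd`, `mi`,
#'   `dice_oracle`, `chosen`.
#' @export
as.data.frame.medbridge_selection <- function(x, ...) {
  data.frame(
    mediator_id = vapply(x$candidates, function(cd) cd$mediator_id, character(1)),
    ssd = vapply(x$candidates, function(cd) cd$ssd, numeric(1)),
    mi = vapply(x$candidates, function(cd) cd$mi, numeric(1)),
    dice_oracle = vapply(x$candidates, function(cd) cd$dice_oracle, numeric(1)),
    chosen = vapply(x$candidates, function(cd)
      identical(cd$mediator_id, x$chosen_id), logical(1)),
    stringsAsFactors = FALSE)
}

#' Carry a subject image or mask into the template space
#'
#' Resamples onto the template grid through a composed subject-to-template
#' transform: trilinear interpolation for images, nearest-neighbour for masks
#' (so values stay exactly 0/1).
#'
#' @param subject_or_mask `medbridge_volume` or `medbridge_mask`.
#' @param composed pull-back `medbridge_transform`, subject -> template.
#' @param library the `medbridge_library` whose template grid is the target.
#' @param interpolation override of the class-based default.
#' @return Volume or mask on the template grid.
#' @export
apply_to_template <- function(subject_or_mask, composed, library,
                              interpolation = if (inherits(subject_or_mask,
                                                           "medbridge_mask"))
                                "nearest" else "trilinear") {
  stopifnot(inherits(library, "medbridge_library"))
  resample(subject_or_mask, library$template, composed,
           interpolation = interpolation)
}
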