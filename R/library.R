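#' Construct a mediator library
#'
#' A mediator library is the knowledge base of the workflow: a template
#' volume (with brain mask) defining the target space, plus an ordered set of
#' mediator entries, each a volume with a pre-determined affine transform
#' into the template space (and optionally its own brain mask).
#'
#' @param template `medbridge_volume`, the target-space image.
#' @param template_mask `medbridge_mask` for the template brain.
#' @param entries list of entries built by [mediator_entry()].
#' @param space_label label of the template space (e.g. `"template"`).
#' @return An object of class `medbridge_library`.
#' @export
mediator_library <- function(template, template_mask, entries,
                             space_label = "template") {
  stopifnot(inherits(template, "medbridge_volume"),
            inherits(template_mask, "medbridge_mask"))
  ids <- vapply(entries, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate mediator ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (e in entries) {
    if (!identical(e$to_template$to_space, space_label))
      stop(sprintf("mediator '%s': transform targets space '%s', library space is '%s'",
                   e$id, e$to_template$to_space, space_label))
  }
  structure(list(template = template, template_mask = template_mask,
                 entries = entries, space_label = space_label),
            class = "medbridge_library")
}

#' Construct one mediator entry
#'
#' @param id unique string identifier.
#' @param volume mediator `medbridge_volume`.
#' @param to_template pull-back `medbridge_transform` from the mediator space
#'   into the library's template space.
#' @param mask optional `medbridge_mask` of the mediator brain.
#' @return A list of class `medbridge_mediator_entry`.
#' @export
mediator_entry <- function(id, volume, to_template, mask = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            inherits(volume, "medbridge_volume"),
            inherits(to_template, "medbridge_transform"))
  if (!is.null(mask)) stopifnot(inherits(mask, "medbridge_mask"))
  structure(list(id = id, volume = volume, to_template = to_template,
                 mask = mask),
            class = "medbridge_mediator_entry")
}

#' @export
print.medbridge_library <- function(x, ...) {
  cat(sprintf("<mediator library> space '%s', %d mediators, template %s\n",
              x$space_label, length(x$entries),
              paste(x$template$shape, collapse = "x")))
  invisible(x)
}

#' Number of mediators in a library
#' @param x a `medbridge_library`.
#' @export
length.medbridge_library <- function(x) length(x$entries)

library_ids <- function(library) {
  vapply(library$entries, function(e) e$id, character(1))
}

#' Load a mediator library from a JSON manifest
#'
#' The manifest pairs each mediator volume with its pre-determined
#' mediator-to-template transform:
#' `{"space": str, "template": path, "template_mask": path,
#'   "mediators": [{"id", "volume", "transform", "mask"?}]}`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the manifest JSON.
#' @return A `medbridge_library` with entries in manifest order.
#' @export
load_library <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("file not found: ", manifest_path)
  j <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  need <- c("space", "template", "template_mask", "mediators")
  if (!all(need %in% names(j)))
    stop("malformed manifest (need ", paste(need, collapse = ", "), ")")
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  template <- read_volume(resolve(j$template))
  template_mask <- read_mask(resolve(j$template_mask))
  entries <- lapply(j$mediators, function(m) {
    if (is.null(m$id) || is.null(m$volume) || is.null(m$transform))
      stop("manifest mediator entry needs id, volume and transform")
    mediator_entry(
      id = m$id,
      volume = read_volume(resolve(m$volume)),
      to_template = read_transform(resolve(m$transform)),
      mask = if (!is.null(m$mask)) read_mask(resolve(m$mask)))
  })
  mediator_library(template, template_mask, entries, space_label = j$space)
}

#' Write a mediator library to disk as NIfTI/JSON files plus a manifest
#'
#' @param library a `medbridge_library`.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "medbridge_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(library$template, file.path(dir, "template.nii.gz"))
  write_volume(library$template_mask, file.path(dir, "template_mask.nii.gz"))
  meds <- lapply(library$entries, function(e) {
    vfile <- paste0(e$id, ".nii.gz")
    tfile <- paste0(e$id, "_to_template.json")
    write_volume(e$volume, file.path(dir, vfile))
    write_transform(e$to_template, file.path(dir, tfile))
    rec <- list(id = e$id, volume = vfile, transform = tfile)
    if (!is.null(e$mask)) {
      mfile <- paste0(e$id, "_mask.nii.gz")
      write_volume(e$mask, file.path(dir, mfile))
      rec$mask <- mfile
    }
    rec
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(space = library$space_label, template = "template.nii.gz",
         template_mask = "template_mask.nii.gz", mediators = meds),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
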