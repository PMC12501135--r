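# ---------------------------------------------------------------------------
# File-format glue: columnar spectra TSVs with a session manifest, trial
# tables, NIfTI volumes, JSON results.
# ---------------------------------------------------------------------------

#' Write an edited session to columnar TSV spectra plus a manifest
#'
#' One `ppm intensity` TSV per average; a `manifest.json` records each
#' file's `kind` (ON/OFF/WATER), `pair_index` and the TR.
#'
#' @param session An `edited_session`.
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_spectra_session <- function(session, dir) {
  stopifnot(inherits(session, "edited_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  wr <- function(spec, file, kind, pair) {
    utils::write.table(data.frame(ppm = spec$ppm, intensity = spec$intensity),
                       file.path(dir, file), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    list(file = file, kind = kind, pair_index = pair)
  }
  for (k in seq_along(session$on)) {
    entries[[length(entries) + 1]] <-
      wr(session$on[[k]], sprintf("on_%03d.tsv", k), "ON", k)
    entries[[length(entries) + 1]] <-
      wr(session$off[[k]], sprintf("off_%03d.tsv", k), "OFF", k)
  }
  entries[[length(entries) + 1]] <- wr(session$water, "water.tsv", "WATER", NA)
  manifest <- list(condition = session$design$condition,
                   tr_s = session$design$tr_s,
                   n_on_off_pairs = session$design$n_on_off_pairs,
                   tissue = unclass(session$tissue),
                   spectra = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an edited session written by [write_spectra_session()]
#' @param dir Session directory containing `manifest.json`.
#' @return An `edited_session`.
#' @export
read_spectra_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sp <- manifest$spectra
  rd <- function(file, kind) {
    d <- utils::read.delim(file.path(dir, file))
    spectrum(d$ppm, d$intensity, kind)
  }
  on_rows <- sp[sp$kind == "ON", ]; on_rows <- on_rows[order(on_rows$pair_index), ]
  off_rows <- sp[sp$kind == "OFF", ]; off_rows <- off_rows[order(off_rows$pair_index), ]
  on <- lapply(on_rows$file, rd, kind = "ON")
  off <- lapply(off_rows$file, rd, kind = "OFF")
  water <- rd(sp$file[sp$kind == "WATER"][1], "WATER")
  design <- session_design(manifest$condition,
                           n_on_off_pairs = manifest$n_on_off_pairs,
                           tr_s = manifest$tr_s)
  structure(list(on = on, off = off, water = water, ppm = on[[1]]$ppm,
                 design = design,
                 tissue = tissue_fractions(manifest$tissue$f_gm,
                                           manifest$tissue$f_wm,
                                           manifest$tissue$f_csf)),
            class = "edited_session")
}

#' Write a behavioral trial table as TSV
#' @param trials Data.frame `trial block type responded rt_ms`.
#' @param file Output path.
#' @export
write_trials_tsv <- function(trials, file) {
  utils::write.table(trials[, c("trial", "block", "type", "responded",
                                "rt_ms")],
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a behavioral trial table TSV
#' @param file Path to a TSV with header `trial block type responded rt_ms`.
#' @return Data.frame.
#' @export
read_trials_tsv <- function(file) {
  d <- utils::read.delim(file)
  d$responded <- as.logical(d$responded)
  d
}

#' Write a 4D volume as NIfTI-1
#' @param volume 3D or 4D array.
#' @param file Output `.nii` / `.nii.gz` path.
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @export
write_volume_nifti <- function(volume, file, voxel_size_mm = 3) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI volume as a plain array
#' @param file NIfTI path.
#' @return Array.
#' @export
read_volume_nifti <- function(file) {
  as.array(RNifti::readNifti(file))
}
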