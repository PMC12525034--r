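## File interchange: 16-bit TIFF raw stacks with a YAML manifest, and
## plain-text (JSON/CSV) LUT serialization.

#' Write raw PhaseImageSets as 16-bit TIFFs plus a YAML manifest
#'
#' Filename convention: \code{{role}_{wavelength}nm_fx{fx}_{tag}.tif} with tag
#' on/off (DC) or phi1..phi4 (AC).  The manifest lists every frame with its
#' condition; on conflict with filenames the manifest wins when reading back.
#' Frame values are rounded to 16-bit counts.
#'
#' @param raw list with \code{sample}/\code{phantom} PhaseImageSet lists as
#'   produced by \code{\link{renderRaw}}
#' @param dir output directory (created if needed)
#' @return invisibly the manifest path
#' @export
writeRawDir <- function(raw, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(pixel_pitch = NULL, frames = list())
  for (role in c("sample", "phantom")) {
    for (key in names(raw[[role]])) {
      ps <- raw[[role]][[key]]
      manifest$pixel_pitch <- ps@pixel_pitch
      for (tag in names(ps@frames)) {
        fn <- sprintf("%s_%gnm_fx%g_%s.tif", role, ps@wavelength, ps@fx, tag)
        img <- pmin(pmax(round(ps@frames[[tag]]), 0), 65535)
        tiff::writeTIFF(img / 65535, file.path(dir, fn),
                        bits.per.sample = 16, compression = "none")
        manifest$frames[[length(manifest$frames) + 1]] <- list(
          file = fn, role = role, wavelength = ps@wavelength,
          fx = ps@fx, tag = tag)
      }
    }
  }
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read raw PhaseImageSets back from a manifest
#'
#' @param manifest path to the YAML manifest written by \code{\link{writeRawDir}}
#' @return list with \code{sample} and \code{phantom} PhaseImageSet lists
#' @export
readRawDir <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  out <- list(sample = list(), phantom = list())
  df <- do.call(rbind, lapply(m$frames, as.data.frame))
  for (role in unique(df$role)) {
    sub <- df[df$role == role, ]
    for (key in unique(paste(sub$wavelength, sub$fx))) {
      rows <- sub[paste(sub$wavelength, sub$fx) == key, ]
      frames <- lapply(seq_len(nrow(rows)), function(i) {
        img <- tiff::readTIFF(file.path(dir, rows$file[i]))
        round(img * 65535)
      })
      names(frames) <- rows$tag
      k <- sprintf("w%g_fx%g", rows$wavelength[1], rows$fx[1])
      out[[role]][[k]] <- phaseImageSet(rows$wavelength[1], rows$fx[1],
                                        frames, m$pixel_pitch)
    }
  }
  out
}

#' Serialize a reflectance LUT to JSON
#'
#' Single-file plain-text serialization carrying the grids, the reflectance
#' array and all build metadata; round-trips through \code{\link{readLUT}}.
#'
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param path output path (.json)
#' @return invisibly the path
#' @export
writeLUT <- function(lut, path) {
  stopifnot(is(lut, "ReflectanceLUT"))
  obj <- list(mu_a_grid = lut@mu_a_grid, mu_s_prime_grid = lut@mu_s_prime_grid,
              fx_list = lut@fx_list, R = as.vector(lut@R), dim = dim(lut@R),
              meta = lut@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLUT
#' @export
readLUT <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ReflectanceLUT", mu_a_grid = obj$mu_a_grid,
      mu_s_prime_grid = obj$mu_s_prime_grid, fx_list = obj$fx_list,
      R = array(obj$R, dim = obj$dim), meta = as.list(obj$meta))
}

#' Export a LUT as a long-format CSV for inspection
#'
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param path output path (.csv)
#' @return invisibly the path
#' @export
lutToCSV <- function(lut, path) {
  stopifnot(is(lut, "ReflectanceLUT"))
  g <- expand.grid(mu_a = lut@mu_a_grid, mu_s_prime = lut@mu_s_prime_grid,
                   fx = lut@fx_list)
  g$R <- as.vector(lut@R)
  write.csv(g, path, row.names = FALSE)
  invisible(path)
}
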