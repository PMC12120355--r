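#' Write a voxel grid as a pair of NRRD volumes
#'
#' Two companion single-file NRRD volumes with identical geometry headers:
#' `<prefix>_labels.nrrd` (int32 tissue codes) and `<prefix>_density.nrrd`
#' (double, g/cm^3). Raw little-endian encoding; spacing and origin are
#' written at full double precision so a read round-trip is exact.
#'
#' @param grid A [voxel_grid()].
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_voxel_grid <- function(grid, prefix) {
  paths <- c(labels = paste0(prefix, "_labels.nrrd"),
             density = paste0(prefix, "_density.nrrd"))
  write_nrrd(grid$tissue, paths["labels"], grid$spacing, grid$origin)
  write_nrrd(grid$density, paths["density"], grid$spacing, grid$origin)
  invisible(paths)
}

#' Read a voxel grid written by [write_voxel_grid()]
#' @param prefix Path prefix used when writing.
#' @return A [voxel_grid()].
#' @export
read_voxel_grid <- function(prefix) {
  lab <- read_nrrd(paste0(prefix, "_labels.nrrd"))
  den <- read_nrrd(paste0(prefix, "_density.nrrd"))
  voxel_grid(lab$data, den$data, spacing = lab$spacing, origin = lab$origin)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a 3D array as a raw-encoded NRRD file
#'
#' Minimal NRRD writer (detached headers and compressed encodings are not
#' supported): int32 for integer arrays, double for numeric, raw
#' little-endian data, `space directions` / `space origin` carrying the
#' voxel spacing and first-voxel-center position in mm.
#'
#' @param x 3D array (integer or double).
#' @param path Output path.
#' @param spacing,origin Grid geometry, mm.
#' @export
write_nrrd <- function(x, path, spacing, origin) {
  is_int <- is.integer(x)
  d <- dim(x)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    paste0("type: ", if (is_int) "int32" else "double"),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    paste0("space directions: (", fmt_full(spacing[1]), ",0,0) (0,",
           fmt_full(spacing[2]), ",0) (0,0,", fmt_full(spacing[3]), ")"),
    paste0("space origin: (", paste(fmt_full(origin), collapse = ","), ")"),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(x), con, size = if (is_int) 4L else 8L,
           endian = "little")
  invisible(path)
}

#' Read a raw-encoded NRRD file written by [write_nrrd()]
#' @param path NRRD path.
#' @return List with `data` (3D array), `spacing`, `origin`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    hdr <- c(hdr, line)
  }
  get_field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  type <- get_field("type")
  sizes <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  nums <- function(s) as.numeric(regmatches(s, gregexpr("[-0-9.eE+]+", s))[[1]])
  dirs <- nums(get_field("space directions"))
  spacing <- c(dirs[1], dirs[5], dirs[9])
  origin <- nums(get_field("space origin"))
  n <- prod(sizes)
  data <- if (type == "int32") {
    readBin(con, "integer", n = n, size = 4L, endian = "little")
  } else {
    readBin(con, "double", n = n, size = 8L, endian = "little")
  }
  list(data = array(data, dim = sizes), spacing = spacing, origin = origin)
}

#' Write a treatment plan to YAML
#' @param plan A [build_plan()] plan.
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  ser <- list(
    modality = plan$modality,
    nominal_energy_mv = plan$nominal_energy_mv,
    isocenter = as.list(plan$isocenter),
    sad = plan$sad,
    fractions = plan$fractions,
    beams = lapply(plan$beams, function(b) {
      list(name = b$name,
           gantry_deg = b$control_points$gantry_deg,
           mu_weights = b$control_points$mu_weight,
           mu_total = b$mu_total,
           aperture = list(cell_mm = b$aperture$cell_mm,
                           mask = apply(b$aperture$mask, 1,
                                        function(r) paste(as.integer(r),
                                                          collapse = ""))))
    })
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a treatment plan from YAML written by [write_plan()]
#' @param path YAML path.
#' @return A `treatment_plan`.
#' @export
read_plan <- function(path) {
  y <- yaml::read_yaml(path)
  beams <- lapply(y$beams, function(b) {
    mask <- do.call(rbind, lapply(b$aperture$mask, function(r) {
      as.integer(strsplit(r, "")[[1]]) == 1L
    }))
    list(name = b$name, gantry_deg = NULL,
         n_cp = length(b$gantry_deg),
         mu_total = b$mu_total,
         mu_weights = b$mu_weights,
         gantry_seq = b$gantry_deg,
         aperture = list(mask = mask, cell_mm = b$aperture$cell_mm))
  })
  plan <- build_plan(list(
    modality = y$modality, nominal_energy_mv = y$nominal_energy_mv,
    isocenter = unlist(y$isocenter), sad = y$sad, fractions = y$fractions,
    beams = lapply(beams, function(b) {
      list(name = b$name, gantry_start = b$gantry_seq[1],
           gantry_stop = b$gantry_seq[length(b$gantry_seq)],
           n_cp = b$n_cp, mu_total = b$mu_total, mu_weights = b$mu_weights,
           aperture = b$aperture)
    })
  ))
  # restore the exact gantry sequence (wrap-around arcs are not linear)
  for (i in seq_along(plan$beams)) {
    plan$beams[[i]]$control_points$gantry_deg <- beams[[i]]$gantry_seq
  }
  plan
}

#' Persist a photon bank or exit-record table
#'
#' Columnar persistence via Apache Arrow parquet.
#'
#' @param bank Tibble (photon bank or exit records).
#' @param path Output `.parquet` path.
#' @export
write_photon_bank <- function(bank, path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("the 'arrow' package is required to persist photon banks")
  }
  arrow::write_parquet(bank, path)
  invisible(path)
}

#' Read a photon bank written by [write_photon_bank()]
#' @param path Parquet path.
#' @export
read_photon_bank <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("the 'arrow' package is required to read photon banks")
  }
  as_tibble(arrow::read_parquet(path))
}

#' Write a property table as CSV
#' @param props Optical or radiological property tibble.
#' @param path Output path.
#' @export
write_property_table <- function(props, path) {
  utils::write.csv(props, path, row.names = FALSE)
  invisible(path)
}

#' Read a property table CSV
#' @param path CSV path.
#' @return Tibble.
#' @export
read_property_table <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
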