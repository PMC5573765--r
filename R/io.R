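#' Read / write a sampled waveform as CSV
#'
#' Two-column CSV with header `time_s,value`.
#'
#' @param path File path.
#' @param waveform A [sampled_waveform()] (for writing).
#' @param units Unit metadata attached on read.
#' @return `read_waveform_csv` returns a [sampled_waveform()];
#'   `write_waveform_csv` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path, units = NULL) {
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("waveform CSV needs columns time_s, value")
  sampled_waveform(df$time_s, df$value, units = units)
}

#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "sampled_waveform"))
  write.csv(data.frame(time_s = waveform$times, value = waveform$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write a Fourier waveform as JSON
#'
#' Schema: `{period_s, mean, harmonics: [{re, im}, ...], flow_units}`.
#'
#' @param path File path.
#' @param waveform A [fourier_waveform()] (for writing).
#' @return `read_fourier_json` returns a [fourier_waveform()];
#'   `write_fourier_json` returns `path` invisibly.
#' @export
read_fourier_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  h <- if (length(x$harmonics)) complex(real = x$harmonics$re,
                                        imaginary = x$harmonics$im)
       else complex(0)
  fourier_waveform(x$period_s, x$mean, h,
                   flow_units = x$flow_units %||% "m3_s")
}

#' @rdname read_fourier_json
#' @export
write_fourier_json <- function(waveform, path) {
  stopifnot(inherits(waveform, "fourier_waveform"))
  obj <- list(period_s = waveform$period, mean = waveform$mean_flow,
              harmonics = data.frame(re = Re(waveform$harmonics),
                                     im = Im(waveform$harmonics)),
              flow_units = waveform$flow_units)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write Windkessel parameters as JSON
#'
#' Clinical-unit schema mirroring the packaged parameter table: fields
#' `R1_RAO, R2_RAO, C_RAO, R1_UAO, R2_UAO, C_UAO, R1_VO, R2_VO, C_VO`
#' plus `tie_rao_uao`.
#'
#' @param path File path.
#' @param wk A [windkessel_set()] (for writing).
#' @return `read_windkessel_json` returns a [windkessel_set()];
#'   `write_windkessel_json` returns `path` invisibly.
#' @export
read_windkessel_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  windkessel_set(
    rao = windkessel_terminal(p$R1_RAO, p$R2_RAO, p$C_RAO),
    vo = windkessel_terminal(p$R1_VO, p$R2_VO, p$C_VO),
    uao = windkessel_terminal(p$R1_UAO, p$R2_UAO, p$C_UAO),
    tie_rao_uao = isTRUE(p$tie_rao_uao %||% TRUE))
}

#' @rdname read_windkessel_json
#' @export
write_windkessel_json <- function(wk, path) {
  stopifnot(inherits(wk, "windkessel_set"))
  obj <- list(R1_RAO = wk$rao$R1, R2_RAO = wk$rao$R2, C_RAO = wk$rao$C,
              R1_UAO = wk$uao$R1, R2_UAO = wk$uao$R2, C_UAO = wk$uao$C,
              R1_VO = wk$vo$R1, R2_VO = wk$vo$R2, C_VO = wk$vo$C,
              tie_rao_uao = wk$tie_rao_uao)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a network solution as CSV
#'
#' One row per stored instant; columns `time_s`, the node pressures and the
#' branch flows.
#'
#' @param sol A `network_solution`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(sol, path) {
  stopifnot(inherits(sol, "network_solution"))
  write.csv(cbind(data.frame(time_s = sol$times), sol$node_pressures,
                  sol$branch_flows),
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write a labelled surface mesh as ASCII PLY
#'
#' Standard ASCII PLY with vertex `x y z` properties and per-face
#' `vertex_indices` lists plus an integer `region` property; the
#' label-to-integer mapping is stored in header comments
#' (`comment region <int> <label>`). An optional integer `quad_label` face
#' property carries a quad-map classification.
#'
#' @param mesh A [surface_mesh()].
#' @param path File path.
#' @param quad_map Optional [classify_wall()] result to store per face.
#' @return `write_mesh_ply` returns `path` invisibly; `read_mesh_ply`
#'   returns a [surface_mesh()] (with attribute `quad_label` if present).
#' @export
write_mesh_ply <- function(mesh, path, quad_map = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  regions <- sort(unique(mesh$region))
  rid <- match(mesh$region, regions) - 1L
  lab_levels <- c("none", "green", "red", "blue", "yellow")
  header <- c(
    "ply", "format ascii 1.0",
    paste("comment region", seq_along(regions) - 1L, regions),
    if (!is.null(quad_map))
      paste("comment quad_label", seq_along(lab_levels) - 1L, lab_levels),
    paste("element vertex", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "property int region",
    if (!is.null(quad_map)) "property int quad_label",
    "end_header")
  vlines <- apply(mesh$vertices, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = " "))
  fmat <- cbind(3L, mesh$faces - 1L, rid)
  if (!is.null(quad_map))
    fmat <- cbind(fmat, match(quad_map$label, lab_levels) - 1L)
  flines <- apply(fmat, 1L, paste, collapse = " ")
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "ply" || !grepl("ascii", lines[2L]))
    stop("only ASCII PLY is supported")
  hend <- which(lines == "end_header")[1L]
  header <- lines[seq_len(hend)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)))
  rcom <- grep("^comment region ", header, value = TRUE)
  rmap <- do.call(rbind, strsplit(sub("^comment region ", "", rcom), " "))
  has_quad <- any(grepl("^property int quad_label", header))
  vl <- lines[hend + seq_len(nv)]
  verts <- matrix(as.numeric(unlist(strsplit(vl, " +"))), ncol = 3L,
                  byrow = TRUE)
  fl <- lines[hend + nv + seq_len(nf)]
  fparts <- strsplit(fl, " +")
  fm <- matrix(as.integer(unlist(fparts)), ncol = length(fparts[[1L]]),
               byrow = TRUE)
  faces <- fm[, 2:4, drop = FALSE] + 1L
  region <- rmap[match(fm[, 5L], as.integer(rmap[, 1L])), 2L]
  mesh <- surface_mesh(verts, faces, region)
  if (has_quad) attr(mesh, "quad_label") <- fm[, 6L]
  mesh
}

#' Read / write ring definitions as JSON
#'
#' Named lists of 1-based face indices.
#'
#' @param rings Named list of integer vectors (for writing).
#' @param path File path.
#' @return `read_rings_json` returns the named list; `write_rings_json`
#'   returns `path` invisibly.
#' @export
read_rings_json <- function(path) {
  lapply(jsonlite::fromJSON(path), as.integer)
}

#' @rdname read_rings_json
#' @export
write_rings_json <- function(rings, path) {
  jsonlite::write_json(rings, path, digits = NA)
  invisible(path)
}

#' Read / write a space-time field
#'
#' Two on-disk dialects: HDF5 (`format = "h5"`; datasets `times` of length
#' n_t and `vectors` of shape `n_t x n_faces x 3`; requires the `rhdf5`
#' package) and a CSV-per-snapshot directory (`format = "csv"`;
#' `times.csv` with column `time_s` plus one `snapshot_%05d.csv` per
#' instant with columns `fx,fy,fz`). The mesh is not stored; supply it on
#' read.
#'
#' @param field A [spacetime_field()] (for writing).
#' @param path File (h5) or directory (csv) path.
#' @param mesh The [surface_mesh()] the stored field lives on (for reading).
#' @param format `"h5"` or `"csv"`.
#' @return `write_field` returns `path` invisibly; `read_field` returns a
#'   [spacetime_field()].
#' @export
write_field <- function(field, path, format = c("h5", "csv")) {
  stopifnot(inherits(field, "spacetime_field"))
  format <- match.arg(format)
  if (format == "h5") {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("the rhdf5 package is required for HDF5 field I/O")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(field$times, path, "times")
    rhdf5::h5write(field$vectors, path, "vectors")
    rhdf5::h5closeAll()
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(time_s = field$times),
              file.path(path, "times.csv"), row.names = FALSE)
    for (i in seq_along(field$times)) {
      write.csv(data.frame(fx = field$vectors[i, , 1L],
                           fy = field$vectors[i, , 2L],
                           fz = field$vectors[i, , 3L]),
                file.path(path, sprintf("snapshot_%05d.csv", i)),
                row.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path, mesh, format = c("h5", "csv")) {
  format <- match.arg(format)
  if (format == "h5") {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("the rhdf5 package is required for HDF5 field I/O")
    times <- as.numeric(rhdf5::h5read(path, "times"))
    vectors <- rhdf5::h5read(path, "vectors")
    rhdf5::h5closeAll()
  } else {
    times <- read.csv(file.path(path, "times.csv"))$time_s
    snaps <- lapply(seq_along(times), function(i)
      as.matrix(read.csv(file.path(path, sprintf("snapshot_%05d.csv", i)))))
    vectors <- array(0, c(length(times), nrow(snaps[[1L]]), 3L))
    for (i in seq_along(times)) vectors[i, , ] <- snaps[[i]]
  }
  spacetime_field(mesh, times, vectors)
}

#' Read / write a centreline as CSV
#'
#' Four-column CSV `x,y,z,radius` in metres.
#'
#' @param path File path.
#' @param c A [centreline()] (for writing).
#' @return `read_centreline_csv` returns a [centreline()];
#'   `write_centreline_csv` returns `path` invisibly.
#' @export
read_centreline_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y", "z", "radius") %in% names(df)))
    stop("centreline CSV needs columns x, y, z, radius")
  centreline(unname(as.matrix(df[, c("x", "y", "z")])), df$radius)
}

#' @rdname read_centreline_csv
#' @export
write_centreline_csv <- function(c, path) {
  stopifnot(inherits(c, "centreline"))
  write.csv(data.frame(x = c$points[, 1L], y = c$points[, 2L],
                       z = c$points[, 3L], radius = c$radius),
            path, row.names = FALSE)
  invisible(path)
}
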