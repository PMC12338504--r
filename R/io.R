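# ---- mesh I/O (STL ASCII/binary, PLY ASCII) -------------------------------

#' Read a triangle mesh from STL or PLY
#'
#' STL (ASCII or binary, autodetected) and ASCII PLY are supported. STL
#' stores no shared vertices, so vertices are merged on read (exact
#' coordinate match). Coordinates are interpreted in the given units and
#' returned in meters.
#'
#' @param path file path
#' @param units "m" or "mm" (input rescaled to meters)
#' @return a `triangle_mesh`
#' @export
read_mesh <- function(path, units = c("m", "mm")) {
  units <- match.arg(units)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "ply") read_ply(path) else read_stl(path)
  if (units == "mm") m <- triangle_mesh(m$vertices / 1000, m$faces)
  m
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sz <- file.size(path)
  close(con)
  if (!is.na(ntri) && sz == 84 + 50 * ntri && ntri > 0) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    tri <- matrix(0, ntri, 9L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      tri[i, ] <- rec[4:12]
      readBin(con, "raw", 2L)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl)) stop("not a valid STL file")
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    if (nrow(nums) %% 3L != 0L) stop("truncated ASCII STL")
    tri <- matrix(t(nums), ncol = 9L, byrow = TRUE)
  }
  stl_to_mesh(tri)
}

stl_to_mesh <- function(tri) {
  V <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
             tri[, 7:9, drop = FALSE])
  key <- paste(V[, 1L], V[, 2L], V[, 3L])
  uk <- unique(key)
  idx <- match(key, uk)
  Vu <- V[match(uk, key), , drop = FALSE]
  n <- nrow(tri)
  F <- cbind(idx[seq_len(n)], idx[n + seq_len(n)], idx[2L * n + seq_len(n)])
  triangle_mesh(Vu, F)
}

#' Write a mesh as STL
#' @param mesh a `triangle_mesh`
#' @param path output path
#' @param binary write binary STL (default) or ASCII
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  tri <- mesh_tri_coords(mesh)
  nrm <- mesh$normals
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(tri)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(tri))) {
      writeBin(as.numeric(c(nrm[i, ], tri[i, ])), con, size = 4L,
               endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    out <- c("solid mesh",
             unlist(lapply(seq_len(nrow(tri)), function(i) c(
               sprintf("facet normal %g %g %g", nrm[i, 1L], nrm[i, 2L],
                       nrm[i, 3L]),
               "  outer loop",
               sprintf("    vertex %.9g %.9g %.9g", tri[i, c(1, 4, 7)],
                       tri[i, c(2, 5, 8)], tri[i, c(3, 6, 9)]),
               "  endloop", "endfacet"))),
             "endsolid mesh")
    writeLines(out, path)
  }
  invisible(path)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (txt[1L] != "ply") stop("not a PLY file")
  endh <- which(txt == "end_header")[1L]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", txt, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", txt, value = TRUE)[1L]))
  vl <- txt[(endh + 1L):(endh + nv)]
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[1:3])))
  fl <- txt[(endh + nv + 1L):(endh + nv + nf)]
  F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    if (as.integer(p[1L]) != 3L) stop("only triangle faces supported")
    as.integer(p[2:4]) + 1L
  }))
  triangle_mesh(V, F)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `triangle_mesh`
#' @param path output path
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces - 1L
  out <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header",
           sprintf("%.17g %.17g %.17g", V[, 1L], V[, 2L], V[, 3L]),
           sprintf("3 %d %d %d", F[, 1L], F[, 2L], F[, 3L]))
  writeLines(out, path)
  invisible(path)
}

# ---- montage and events ---------------------------------------------------

#' Read an electrode montage from tab-separated text
#'
#' Expected header: `label x y z role` (coordinates in meters); an
#' optional `contact_radius` column overrides the default.
#'
#' @param path file path
#' @param contact_radius default contact radius (m)
#' @return an `electrode_montage`
#' @export
read_montage <- function(path, contact_radius = 0.005) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "role")
  if (!all(need %in% names(df)))
    stop("montage file must have columns: label x y z role")
  cr <- if ("contact_radius" %in% names(df)) df$contact_radius
        else contact_radius
  electrode_montage(df$label, cbind(df$x, df$y, df$z), df$role, cr)
}

#' Write an electrode montage as tab-separated text
#' @param montage an `electrode_montage`
#' @param path output path
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read events from tab-separated text (columns: sample, code)
#' @param path file path
#' @return data.frame
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write events as tab-separated text
#' @param events data.frame with `sample` and `code`
#' @param path output path
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- recordings -----------------------------------------------------------

#' Write a recording as a delimited matrix plus JSON header
#'
#' Data go to `<path>` (samples x channels, tab-separated); sampling rate,
#' labels, reference and events go to `<path>.json`.
#'
#' @param rec an `eeg_recording`
#' @param path output path for the data matrix
#' @export
write_recording <- function(rec, path) {
  utils::write.table(t(rec$data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = rec$labels)
  hdr <- list(fs = rec$fs, labels = rec$labels,
              reference = rec$reference, events = rec$events)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#' @param path path of the data matrix (JSON header at `<path>.json`)
#' @return an `eeg_recording`
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  ev <- as.data.frame(hdr$events)
  eeg_recording(t(as.matrix(df)), hdr$fs, hdr$labels, ev, hdr$reference)
}

#' Minimal EDF reader
#'
#' Reads European Data Format (EDF/EDF+C) files with equal sampling rates
#' across signals; annotation channels are skipped. Values are converted
#' to physical units via the per-signal calibration and interpreted as
#' volts (with microvolt dimension labels rescaled).
#'
#' @param path EDF file path
#' @return an `eeg_recording` (without events)
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8L)                       # version
  rd(80L); rd(80L)             # patient, recording id
  rd(8L); rd(8L)               # start date, time
  as.integer(rd(8L))           # header bytes
  rd(44L)                      # reserved
  ndr <- as.integer(rd(8L))    # number of data records
  dur <- as.numeric(rd(8L))    # record duration (s)
  ns <- as.integer(rd(4L))     # number of signals
  lab <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  vapply(seq_len(ns), function(i) rd(80L), character(1))   # transducer
  dim_ <- vapply(seq_len(ns), function(i) rd(8L), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  vapply(seq_len(ns), function(i) rd(80L), character(1))   # prefiltering
  nspr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  vapply(seq_len(ns), function(i) rd(32L), character(1))   # reserved
  keep <- !grepl("Annotations", lab)
  if (length(unique(nspr[keep])) != 1L)
    stop("signals with differing sampling rates are not supported")
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  offs <- pmin_ - scale * dmin
  data <- matrix(0, sum(keep), ndr * nspr[keep][1L])
  for (r in seq_len(ndr)) {
    ki <- 0L
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", nspr[s], size = 2L, endian = "little")
      if (keep[s]) {
        ki <- ki + 1L
        idx <- ((r - 1L) * nspr[s] + 1L):(r * nspr[s])
        data[ki, idx] <- v * scale[s] + offs[s]
      }
    }
  }
  uv <- grepl("uV|µV", dim_[keep])
  data[uv, ] <- data[uv, ] * 1e-6
  fs <- nspr[keep][1L] / dur
  eeg_recording(data, fs, make.unique(lab[keep]))
}

# ---- lead fields and inverse operators ------------------------------------

#' Write a lead field (binary matrix + JSON sidecar)
#'
#' The matrix goes to `<path>` as little-endian doubles (column-major,
#' preceded by two int32 dimensions); labels, reference, flags, the
#' stored PCA component and source metadata go to `<path>.json`.
#'
#' @param L a `leadfield`
#' @param path output path
#' @export
write_leadfield <- function(L, path) {
  con <- file(path, "wb")
  writeBin(dim(L$matrix), con, size = 4L, endian = "little")
  writeBin(as.numeric(L$matrix), con, size = 8L, endian = "little")
  close(con)
  meta <- list(channel_labels = L$channel_labels, ref_label = L$ref_label,
               source_id = L$source_space$id,
               source_index = L$source_index,
               pca_corrected = L$pca_corrected,
               reference_scheme = L$reference_scheme, u = L$u,
               checksum = leadfield_checksum(L$matrix))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

leadfield_checksum <- function(M) {
  v <- c(dim(M), sum(M), sum(M^2))
  sprintf("%.17g", sum(v * seq_along(v)))
}

#' Read a lead field written by [write_leadfield()]
#'
#' The binary matrix round-trips bit-exactly; a checksum mismatch (or a
#' truncated file) raises an error rather than returning silently
#' corrupted data. The source-space geometry is not stored in the file;
#' supply it to re-attach positions.
#'
#' @param path file path
#' @param source_space optional `source_space` to attach
#' @param montage optional `electrode_montage` to attach
#' @return a `leadfield`
#' @export
read_leadfield <- function(path, source_space = NULL, montage = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  if (length(d) != 2L || any(d <= 0)) stop("corrupt lead-field file")
  v <- readBin(con, "numeric", prod(d), size = 8L, endian = "little")
  if (length(v) != prod(d)) stop("truncated lead-field file")
  M <- matrix(v, d[1L], d[2L])
  if (!identical(leadfield_checksum(M), meta$checksum))
    warning("lead-field checksum mismatch")
  ss <- if (!is.null(source_space)) source_space else
    structure(list(positions = NULL, id = meta$source_id),
              class = "source_space")
  new_leadfield(M, meta$channel_labels, meta$ref_label, ss,
                meta$source_index, montage,
                pca_corrected = meta$pca_corrected,
                reference_scheme = meta$reference_scheme,
                u = if (is.null(meta$u)) NULL else as.numeric(meta$u))
}

#' Write ground truth metadata as JSON
#' @param truth a `ground_truth`
#' @param path output path
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read ground truth metadata
#' @param path JSON path
#' @return a `ground_truth`
#' @export
read_ground_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "ground_truth")
}

# ---- inverse operators ----------------------------------------------------

#' Write an inverse operator (binary arrays + JSON sidecar)
#'
#' The whitener, kernel and depth prior go to `<path>` as little-endian
#' doubles; parameters (gamma, lambda, exponent rule, condition number,
#' dSPM normalizers, channel labels) go to `<path>.json`.
#'
#' @param op an `inverse_operator`
#' @param path output path
#' @export
write_inverse_operator <- function(op, path) {
  con <- file(path, "wb")
  wmat <- function(M) {
    writeBin(dim(M), con, size = 4L, endian = "little")
    writeBin(as.numeric(M), con, size = 8L, endian = "little")
  }
  wmat(op$whitener)
  wmat(op$kernel)
  wmat(op$noise_sigma)
  close(con)
  meta <- list(gamma = op$gamma, lambda = op$lambda, scale = op$scale,
               exponent = op$exponent, cond = op$cond,
               R = op$R, dspm_normalizers = op$dspm_normalizers,
               channel_labels = op$channel_labels,
               source_index = op$source_index)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an inverse operator written by [write_inverse_operator()]
#' @param path file path
#' @param source_space optional `source_space` to attach
#' @return an `inverse_operator`
#' @export
read_inverse_operator <- function(path, source_space = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  rmat <- function() {
    d <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    v <- readBin(con, "numeric", prod(d), size = 8L, endian = "little")
    if (length(v) != prod(d)) stop("truncated inverse-operator file")
    matrix(v, d[1L], d[2L])
  }
  W <- rmat(); K <- rmat(); S <- rmat()
  structure(list(whitener = W, Lhat = NULL, R = as.numeric(meta$R),
                 gamma = meta$gamma, lambda = meta$lambda,
                 scale = meta$scale, kernel = K,
                 dspm_normalizers = as.numeric(meta$dspm_normalizers),
                 exponent = meta$exponent, noise_sigma = S,
                 cond = meta$cond,
                 channel_labels = meta$channel_labels,
                 source_space = source_space,
                 source_index = as.integer(meta$source_index)),
            class = "inverse_operator")
}
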