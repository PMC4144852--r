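# File interchange: multi-page 32-bit float TIFF (hand-rolled baseline
# writer/reader -- no TIFF package exists in the supported stack), the
# truth-network JSON schema, and CSV round trips for physiology tables.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

ifd_entry <- function(tag, type, count, value_raw4) {
  c(u16(tag), u16(type), u32(count), value_raw4)
}
short_val <- function(x) c(u16(x), u16(0))

#' Write channels as an uncompressed multi-page float TIFF
#'
#' Baseline little-endian TIFF, one grayscale 32-bit IEEE-float page per
#' channel, one strip per page, pixel size recorded as X/YResolution in
#' pixels per centimetre and echoed in each page's ImageDescription.  A
#' sidecar `<path>.json` stores the channel names and, for synthetic
#' images, the generating spec and seed.
#'
#' @param image a `synthetic_image` or list with `channels` (named list of
#'   matrices) and `pixel_size_um`.
#' @param path output file path (`.tif`).
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, sidecar = TRUE) {
  channels <- image$channels
  stopifnot(length(channels) >= 1L, !is.null(names(channels)))
  px <- image$pixel_size_um
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(u16(42L), con)
  first_ifd_pos <- 4L
  writeBin(u32(0L), con)  # patched later
  cur <- 8L
  ifd_offsets <- integer(length(channels))
  blobs <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    m <- channels[[i]]
    H <- nrow(m)
    W <- ncol(m)
    desc <- sprintf('{"channel":"%s","pixel_size_um":%.10g}',
                    names(channels)[i], px)
    desc_raw <- c(charToRaw(desc), as.raw(0))
    if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0))
    data_raw <- writeBin(as.numeric(t(m)), raw(), size = 4, endian = "little")
    data_off <- cur
    xres_off <- data_off + length(data_raw)
    yres_off <- xres_off + 8L
    desc_off <- yres_off + 8L
    ifd_off <- desc_off + length(desc_raw)
    rat <- c(u32(10000000L), u32(as.integer(round(px * 1000))))
    res_raw <- c(rat, rat)  # xres then yres, pixels per cm
    entries <- c(
      ifd_entry(256L, 4L, 1L, u32(W)),
      ifd_entry(257L, 4L, 1L, u32(H)),
      ifd_entry(258L, 3L, 1L, short_val(32L)),
      ifd_entry(259L, 3L, 1L, short_val(1L)),
      ifd_entry(262L, 3L, 1L, short_val(1L)),
      ifd_entry(270L, 2L, length(desc_raw), u32(desc_off)),
      ifd_entry(273L, 4L, 1L, u32(data_off)),
      ifd_entry(277L, 3L, 1L, short_val(1L)),
      ifd_entry(278L, 4L, 1L, u32(H)),
      ifd_entry(279L, 4L, 1L, u32(length(data_raw))),
      ifd_entry(282L, 5L, 1L, u32(xres_off)),
      ifd_entry(283L, 5L, 1L, u32(yres_off)),
      ifd_entry(296L, 3L, 1L, short_val(3L)),
      ifd_entry(339L, 3L, 1L, short_val(3L)))
    ifd <- c(u16(14L), entries, u32(0L))  # next-IFD patched on following page
    writeBin(data_raw, con)
    writeBin(res_raw, con)  # xres then yres
    writeBin(desc_raw, con)
    writeBin(ifd, con)
    ifd_offsets[i] <- ifd_off
    blobs[[i]] <- ifd_off
    cur <- ifd_off + length(ifd)
  }
  # patch the IFD chain
  close(con)
  on.exit()
  con <- file(path, "r+b")
  on.exit(close(con))
  seek(con, first_ifd_pos, rw = "write")
  writeBin(u32(ifd_offsets[1]), con)
  if (length(ifd_offsets) > 1L) {
    for (i in seq_len(length(ifd_offsets) - 1L)) {
      seek(con, ifd_offsets[i] + 2L + 14L * 12L, rw = "write")
      writeBin(u32(ifd_offsets[i + 1L]), con)
    }
  }
  if (sidecar) {
    meta <- list(channels = names(channels), pixel_size_um = px)
    if (!is.null(image$spec)) meta$spec <- unclass(image$spec)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = 12, pretty = TRUE)
  }
  invisible(path)
}

#' Read a float TIFF written by [write_image_tiff()]
#'
#' Parses little-endian baseline TIFF with 32-bit IEEE-float samples
#' (arbitrary strip layout).  Channel names come from each page's
#' ImageDescription (falling back to `page<i>`); pixel size from the
#' resolution tags.
#'
#' @param path TIFF path.
#' @return list with `channels`, `pixel_size_um`, and `spec` (from the
#'   sidecar, when present).
#' @export
read_image_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  ru16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                                size = 2, endian = "little", signed = FALSE)
  ru32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                                size = 4, endian = "little")
  if (rawToChar(raw[1:2]) != "II" || ru16(2) != 42L)
    stop("not a little-endian TIFF")
  channels <- list()
  px <- NA_real_
  ifd <- ru32(4)
  while (ifd != 0L) {
    n <- ru16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2L + (k - 1L) * 12L
      tags[[as.character(ru16(e))]] <-
        list(type = ru16(e + 2L), count = ru32(e + 4L), voff = e + 8L)
    }
    val <- function(tag) {
      tg <- tags[[as.character(tag)]]
      if (is.null(tg)) return(NULL)
      nbytes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)[
        as.character(tg$type)]
      total <- nbytes * tg$count
      off <- if (total <= 4L) tg$voff else ru32(tg$voff)
      if (tg$type == 3L) vapply(seq_len(tg$count), function(i)
        ru16(off + (i - 1L) * 2L), integer(1))
      else if (tg$type == 4L) vapply(seq_len(tg$count), function(i)
        ru32(off + (i - 1L) * 4L), integer(1))
      else if (tg$type == 5L) ru32(off) / ru32(off + 4L)
      else if (tg$type == 2L) {
        s <- raw[(off + 1):(off + tg$count)]
        rawToChar(s[s != as.raw(0)])
      } else NULL
    }
    W <- val(256)
    H <- val(257)
    if (!identical(val(258), 32L) || !identical(val(339), 3L))
      stop("unsupported TIFF sample format (expect 32-bit IEEE float)")
    if (!identical(val(259), 1L)) stop("compressed TIFF not supported")
    soff <- val(273)
    scnt <- val(279)
    vals <- unlist(lapply(seq_along(soff), function(i)
      readBin(raw[(soff[i] + 1):(soff[i] + scnt[i])], "double", size = 4,
              n = scnt[i] / 4L, endian = "little")))
    m <- matrix(vals, nrow = H, ncol = W, byrow = TRUE)
    nm <- paste0("page", length(channels) + 1L)
    desc <- val(270)
    if (!is.null(desc)) {
      meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
      if (!is.null(meta$channel)) nm <- meta$channel
      if (!is.null(meta$pixel_size_um)) px <- meta$pixel_size_um
    }
    if (is.na(px)) {
      xr <- val(282)
      if (!is.null(xr) && identical(val(296), 3L)) px <- 1e4 / xr
    }
    channels[[nm]] <- m
    ifd <- ru32(ifd + 2L + n * 12L)
  }
  out <- list(channels = channels, pixel_size_um = px)
  sc <- paste0(path, ".json")
  if (file.exists(sc))
    out$spec <- tryCatch(jsonlite::read_json(sc, simplifyVector = TRUE)$spec,
                         error = function(e) NULL)
  out
}

#' Serialize a junction network to JSON
#'
#' Schema: `vertices` `[{id, x_um, y_um}]`, `sides`
#' `[{id, v1, v2, polyline: [[x_um, y_um], ...], border}]`, plus
#' `pixel_size_um` and `field_um`.  Coordinates in um, origin top-left,
#' y downward.
#'
#' @param network a [junction_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  obj <- list(
    vertices = lapply(seq_len(nrow(network$vertices)), function(i)
      list(id = network$vertices$id[i], x_um = network$vertices$x_um[i],
           y_um = network$vertices$y_um[i])),
    sides = lapply(network$sides, function(s)
      list(id = s$id, v1 = s$v1, v2 = s$v2,
           polyline = lapply(seq_len(nrow(s$polyline)), function(j)
             c(s$polyline[j, 1], s$polyline[j, 2])),
           border = isTRUE(s$border))),
    pixel_size_um = network$pixel_size_um,
    field_um = network$field_um)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12,
                       na = "null")
  invisible(path)
}

#' Read a junction network from its JSON serialization
#' @param path JSON path written by [write_network_json()].
#' @return a [junction_network()].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  verts <- data.frame(
    id = vapply(obj$vertices, function(v) as.integer(v$id), integer(1)),
    x_um = vapply(obj$vertices, function(v) as.numeric(v$x_um), numeric(1)),
    y_um = vapply(obj$vertices, function(v) as.numeric(v$y_um), numeric(1)))
  sides <- lapply(obj$sides, function(s) {
    poly <- do.call(rbind, lapply(s$polyline, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    list(id = as.integer(s$id), v1 = as.integer(s$v1), v2 = as.integer(s$v2),
         polyline = poly, border = isTRUE(s$border))
  })
  junction_network(verts, sides,
                   pixel_size_um = as.numeric(obj$pixel_size_um %||% NA),
                   field_um = as.numeric(unlist(obj$field_um %||%
                                                  c(NA, NA))))
}

#' Write/read electrophysiology records as CSV
#'
#' One row per measurement; solutions and temperature travel in the table
#' so a file round-trips without sidecars.
#' @param records list of [electro_record()]s.
#' @param path CSV path.
#' @return `path` invisibly; the reader returns a list of records.
#' @export
write_electro_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(raw_resistance_ohm = r$raw_resistance_ohm,
               blank_resistance_ohm = r$blank_resistance_ohm,
               raw_potential_mV = r$raw_potential_mV,
               blank_potential_mV = r$blank_potential_mV,
               area_cm2 = r$area_cm2, temperature_K = r$temperature_K,
               ap_Na = r$apical$Na, ap_K = r$apical$K, ap_Cl = r$apical$Cl,
               bl_Na = r$basolateral$Na, bl_K = r$basolateral$K,
               bl_Cl = r$basolateral$Cl)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electro_csv
#' @export
read_electro_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    electro_record(df$raw_resistance_ohm[i], df$blank_resistance_ohm[i],
                   df$raw_potential_mV[i], df$blank_potential_mV[i],
                   area_cm2 = df$area_cm2[i],
                   apical = ion_solution(Na = df$ap_Na[i], K = df$ap_K[i],
                                         Cl = df$ap_Cl[i], name = "apical"),
                   basolateral = ion_solution(Na = df$bl_Na[i],
                                              K = df$bl_K[i],
                                              Cl = df$bl_Cl[i],
                                              name = "basolateral"),
                   temperature_K = df$temperature_K[i]))
}

#' Write/read a raw flux dataset as CSV
#'
#' The series and the calibration standards share one long-format table
#' with a `kind` column (`sample` rows carry time and fluorescence;
#' `standard` rows carry amount and fluorescence).
#' @param dataset a [generate_flux_dataset()]-shaped list.
#' @param path CSV path.
#' @return `path` invisibly; the reader returns the dataset list.
#' @export
write_flux_csv <- function(dataset, path) {
  s <- dataset$series
  df <- rbind(
    data.frame(kind = "sample", time_h = s$times_h,
               amount_nmol = NA_real_, fluorescence = s$fluorescence,
               area_cm2 = s$area_cm2, C0_mM = s$C0_mM),
    data.frame(kind = "standard", time_h = NA_real_,
               amount_nmol = dataset$standards$amount_nmol,
               fluorescence = dataset$standards$fluorescence,
               area_cm2 = s$area_cm2, C0_mM = s$C0_mM))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_csv
#' @export
read_flux_csv <- function(path) {
  df <- utils::read.csv(path)
  sa <- df[df$kind == "sample", , drop = FALSE]
  st <- df[df$kind == "standard", , drop = FALSE]
  list(series = list(times_h = sa$time_h, fluorescence = sa$fluorescence,
                     area_cm2 = sa$area_cm2[1], C0_mM = sa$C0_mM[1]),
       standards = data.frame(amount_nmol = st$amount_nmol,
                              fluorescence = st$fluorescence))
}
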