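# Minimal DICOM support: enough of Part 10 to read a PET series (for
# body-weight SUV conversion) and an RT Structure Set, plus an internal
# writer used to produce synthetic fixtures. Explicit and implicit VR
# little endian, uncompressed pixel data only. No DICOM package ships
# with this environment, so the byte format is handled directly.

.u16 <- function(r, off) readBin(r[off + 1:2], "integer", size = 2,
                                 endian = "little", signed = FALSE)
.u32 <- function(r, off) {
  v <- readBin(r[off + 1:4], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else v
}

# tag -> VR dictionary for the elements this package interprets (needed
# for implicit-VR files); everything else is carried as raw/unknown
.dicom_dict <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0021" = "DA",
  "0008,0031" = "TM", "0008,0032" = "TM", "0008,0060" = "CS",
  "0010,1030" = "DS", "0018,1072" = "TM", "0018,1074" = "DS",
  "0018,1075" = "DS", "0018,1078" = "DT",
  "0020,000E" = "UI", "0020,0013" = "IS", "0020,0032" = "DS",
  "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0010" = "US", "0028,0011" = "US",
  "0028,0030" = "DS", "0028,0100" = "US", "0028,0101" = "US",
  "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS",
  "0054,0016" = "SQ", "0054,1001" = "CS", "0054,1102" = "CS",
  "3006,0020" = "SQ", "3006,0022" = "IS", "3006,0026" = "LO",
  "3006,0039" = "SQ", "3006,0040" = "SQ", "3006,0042" = "CS",
  "3006,0046" = "IS", "3006,0050" = "DS", "3006,0084" = "IS",
  "7FE0,0010" = "OW")

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.string_vrs <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH",
                 "ST", "TM", "UI")

.decode_value <- function(vr, bytes) {
  if (length(bytes) == 0) return(NULL)
  if (vr %in% c("DS", "IS")) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    return(as.numeric(strsplit(trimws(s), "\\\\")[[1]]))
  }
  if (vr %in% .string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    return(sub("\\s+$", "", s))
  }
  if (vr == "US") return(readBin(bytes, "integer", n = length(bytes) / 2,
                                 size = 2, endian = "little",
                                 signed = FALSE))
  if (vr %in% c("SS")) return(readBin(bytes, "integer",
                                      n = length(bytes) / 2, size = 2,
                                      endian = "little"))
  if (vr %in% c("UL", "SL")) return(readBin(bytes, "integer",
                                            n = length(bytes) / 4, size = 4,
                                            endian = "little"))
  if (vr == "FL") return(readBin(bytes, "double", n = length(bytes) / 4,
                                 size = 4, endian = "little"))
  if (vr == "FD") return(readBin(bytes, "double", n = length(bytes) / 8,
                                 size = 8, endian = "little"))
  bytes  # OB/OW/UN: raw
}

# parse a dataset from `r` between byte offsets pos..end (0-based);
# returns list(elements = named list, pos = next offset)
.parse_dataset <- function(r, pos, end, explicit) {
  out <- list()
  while (pos + 8 <= end) {
    grp <- .u16(r, pos); ele <- .u16(r, pos + 2)
    tag <- sprintf("%04X,%04X", grp, ele)
    if (grp == 0xFFFE) {          # item/sequence delimiters
      len <- .u32(r, pos + 4)
      return(list(elements = out, pos = pos, tag = tag, len = len))
    }
    if (explicit) {
      vr <- rawToChar(r[pos + 5:6])
      if (vr %in% .long_vrs) {
        len <- .u32(r, pos + 8); pos <- pos + 12
      } else {
        len <- .u16(r, pos + 6); pos <- pos + 8
      }
    } else {
      vr <- if (tag %in% names(.dicom_dict)) .dicom_dict[[tag]] else "UN"
      len <- .u32(r, pos + 4); pos <- pos + 8
    }
    undefined <- len == 0xFFFFFFFF
    if (vr == "SQ" || (undefined && vr == "UN")) {
      sq_end <- if (undefined) end else pos + len
      items <- list()
      while (pos + 8 <= sq_end) {
        igrp <- .u16(r, pos); iele <- .u16(r, pos + 2)
        ilen <- .u32(r, pos + 4)
        pos <- pos + 8
        if (igrp == 0xFFFE && iele == 0xE0DD) break      # sequence end
        if (!(igrp == 0xFFFE && iele == 0xE000))
          stop("malformed sequence at offset ", pos - 8)
        item_end <- if (ilen == 0xFFFFFFFF) sq_end else pos + ilen
        res <- .parse_dataset(r, pos, item_end, explicit)
        items[[length(items) + 1L]] <- res$elements
        pos <- res$pos
        if (ilen == 0xFFFFFFFF) {
          # consume the item delimiter found by the child parser
          if (!is.null(res$tag) && res$tag == "FFFE,E00D") pos <- pos + 8
        }
      }
      out[[tag]] <- items
    } else {
      if (undefined) stop("undefined length outside a sequence at ", tag)
      out[[tag]] <- .decode_value(vr, r[pos + seq_len(len)])
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos, tag = NULL)
}

# read one DICOM file -> named element list
read_dicom_file <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  pos <- 0
  explicit <- TRUE
  if (length(r) > 132 && rawToChar(r[129:132]) == "DICM") {
    pos <- 132
    # file meta group (always explicit VR LE)
    meta_end <- length(r)
    meta <- list()
    while (pos + 8 <= length(r) && .u16(r, pos) == 0x0002) {
      res <- .parse_one_meta(r, pos)
      meta[[res$tag]] <- res$value
      pos <- res$pos
    }
    ts <- meta[["0002,0010"]]
    if (!is.null(ts)) {
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("unsupported transfer syntax ", ts,
             " (only uncompressed little endian)")
    }
  }
  .parse_dataset(r, pos, length(r), explicit)$elements
}

.parse_one_meta <- function(r, pos) {
  grp <- .u16(r, pos); ele <- .u16(r, pos + 2)
  vr <- rawToChar(r[pos + 5:6])
  if (vr %in% .long_vrs) {
    len <- .u32(r, pos + 8); pos <- pos + 12
  } else {
    len <- .u16(r, pos + 6); pos <- pos + 8
  }
  list(tag = sprintf("%04X,%04X", grp, ele),
       value = .decode_value(vr, r[pos + seq_len(len)]), pos = pos + len)
}

# ---- encoding (fixture writer) ---------------------------------------

.enc_u16 <- function(v) writeBin(as.integer(v), raw(), size = 2,
                                 endian = "little")
.enc_u32 <- function(v) writeBin(as.integer(v), raw(), size = 4,
                                 endian = "little")

.enc_element <- function(tag, vr, value) {
  grp <- strtoi(substr(tag, 1, 4), 16L); ele <- strtoi(substr(tag, 6, 9), 16L)
  if (vr == "SQ") {
    body <- do.call(c, lapply(value, function(item) {
      ib <- do.call(c, item)
      c(.enc_u16(0xFFFE), .enc_u16(0xE000), .enc_u32(length(ib)), ib)
    }))
    if (is.null(body)) body <- raw(0)
    return(c(.enc_u16(grp), .enc_u16(ele), charToRaw(vr), raw(2),
             .enc_u32(length(body)), body))
  }
  bytes <- if (vr %in% c("DS", "IS"))
    charToRaw(paste(vapply(value, format, "", digits = 12), collapse = "\\"))
  else if (vr %in% .string_vrs) charToRaw(paste(value, collapse = "\\"))
  else if (vr == "US") writeBin(as.integer(value), raw(), size = 2,
                                endian = "little")
  else if (vr == "UL") writeBin(as.integer(value), raw(), size = 4,
                                endian = "little")
  else if (vr == "FD") writeBin(as.double(value), raw(), size = 8,
                                endian = "little")
  else as.raw(value)
  if (length(bytes) %% 2 == 1)
    bytes <- c(bytes, if (vr == "UI") as.raw(0) else charToRaw(" "))
  if (vr %in% .long_vrs)
    c(.enc_u16(grp), .enc_u16(ele), charToRaw(vr), raw(2),
      .enc_u32(length(bytes)), bytes)
  else
    c(.enc_u16(grp), .enc_u16(ele), charToRaw(vr),
      .enc_u16(length(bytes)), bytes)
}

.dicom_file <- function(sop_class, sop_instance, body) {
  meta_body <- c(.enc_element("0002,0002", "UI", sop_class),
                 .enc_element("0002,0003", "UI", sop_instance),
                 .enc_element("0002,0010", "UI", "1.2.840.10008.1.2.1"))
  c(raw(128), charToRaw("DICM"),
    .enc_element("0002,0000", "UL", length(meta_body)), meta_body, body)
}

.uid <- function(...) paste("2.25", paste(..., sep = "."), sep = ".")

#' Write a synthetic PET DICOM series
#'
#' Serializes an activity-concentration volume (Bq/mL) as an uncompressed
#' explicit-VR little-endian PET series with the header fields needed for
#' body-weight SUV conversion. Intended for simulation and testing — the
#' series is synthetic, not scanner output.
#'
#' @param activity 3-D array of activity concentration in Bq/mL.
#' @param dir Output directory (created if needed); one file per slice.
#' @param spacing Voxel spacing mm (x = column, y = row, z = slice).
#' @param origin World position (mm) of the first voxel center.
#' @param weight_kg Patient weight in kg.
#' @param dose_bq Injected dose in Bq (RadionuclideTotalDose).
#' @param injection_time,series_time Clock times `"HHMMSS"` (same day).
#' @param half_life_s Radionuclide half-life in seconds (F-18: 6586.2).
#' @param decay_correction `"START"` (activity already decay-corrected to
#'   the series time, the common case) — recorded in the header.
#' @param series_uid Series Instance UID; default derives one from the
#'   clock. Give distinct values to emulate mixed series.
#' @param omit Tag keys (`"GGGG,EEEE"`) to leave out, for exercising
#'   missing-tag error paths.
#' @return The directory path, invisibly.
#' @export
write_pet_dicom <- function(activity, dir, spacing = c(4, 4, 4),
                            origin = c(0, 0, 0), weight_kg = 70,
                            dose_bq = 3.5e8,
                            injection_time = "100000",
                            series_time = "110000",
                            half_life_s = 6586.2,
                            decay_correction = "START",
                            series_uid = NULL, omit = character(0)) {
  stopifnot(length(dim(activity)) == 3)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(activity)
  # 16-bit storage with a private rescale slope covering the dynamic range
  amax <- max(activity)
  slope <- if (amax > 0) amax / 32000 else 1
  stored <- round(activity / slope)
  if (is.null(series_uid))
    series_uid <- .uid("1", as.integer(Sys.time()) %% 100000000L)
  for (k in seq_len(d[3])) {
    sl <- stored[, , k]
    px <- writeBin(as.integer(as.vector(sl)), raw(), size = 2,
                   endian = "little")
    elems <- list(
      "0008,0016" = .enc_element("0008,0016", "UI",
                                 "1.2.840.10008.5.1.4.1.1.128"),
      "0008,0018" = .enc_element("0008,0018", "UI", .uid("2", k)),
      "0008,0031" = .enc_element("0008,0031", "TM", series_time),
      "0008,0060" = .enc_element("0008,0060", "CS", "PT"),
      "0010,1030" = .enc_element("0010,1030", "DS", weight_kg),
      "0054,0016" = .enc_element("0054,0016", "SQ", list(list(
        .enc_element("0018,1072", "TM", injection_time),
        .enc_element("0018,1074", "DS", dose_bq),
        .enc_element("0018,1075", "DS", half_life_s)))),
      "0020,000E" = .enc_element("0020,000E", "UI", series_uid),
      "0020,0013" = .enc_element("0020,0013", "IS", k),
      "0020,0032" = .enc_element("0020,0032", "DS",
        c(origin[1], origin[2], origin[3] + (k - 1) * spacing[3])),
      "0020,0037" = .enc_element("0020,0037", "DS", c(1, 0, 0, 0, 1, 0)),
      "0028,0002" = .enc_element("0028,0002", "US", 1),
      "0028,0010" = .enc_element("0028,0010", "US", d[2]),   # rows (y)
      "0028,0011" = .enc_element("0028,0011", "US", d[1]),   # columns (x)
      "0028,0030" = .enc_element("0028,0030", "DS",
                                 c(spacing[2], spacing[1])),
      "0028,0100" = .enc_element("0028,0100", "US", 16),
      "0028,0101" = .enc_element("0028,0101", "US", 16),
      "0028,0102" = .enc_element("0028,0102", "US", 15),
      "0028,0103" = .enc_element("0028,0103", "US", 0),
      "0028,1052" = .enc_element("0028,1052", "DS", 0),
      "0028,1053" = .enc_element("0028,1053", "DS", slope),
      "0054,1001" = .enc_element("0054,1001", "CS", "BQML"),
      "0054,1102" = .enc_element("0054,1102", "CS", decay_correction),
      "7FE0,0010" = .enc_element("7FE0,0010", "OW", px))
    body <- do.call(c, unname(elems[setdiff(names(elems), omit)]))
    writeBin(.dicom_file("1.2.840.10008.5.1.4.1.1.128", .uid("2", k), body),
             file.path(dir, sprintf("slice%03d.dcm", k)))
  }
  invisible(dir)
}

.tm_seconds <- function(tm) {
  tm <- sub("\\..*$", "", tm)
  h <- as.numeric(substr(tm, 1, 2)); m <- as.numeric(substr(tm, 3, 4))
  s <- as.numeric(substr(tm, 5, 10))
  if (is.na(s)) s <- 0
  h * 3600 + m * 60 + s
}

#' Read a PET DICOM series and convert to body-weight SUV
#'
#' Reads every `.dcm` file in a directory as one PET series, assembles the
#' slices by position, converts activity concentration (Bq/mL, per the
#' Units header) to body-weight SUV:
#' `SUV = concentration * weight(g) / decay-corrected dose (Bq)`,
#' where the injected dose is decay-corrected from injection time to the
#' series time with the radionuclide half-life from the header — unless
#' the header's decay-correction field says the data are already corrected
#' to the injection time (`"ADMIN"`), in which case no correction is
#' applied (no double correction).
#'
#' @param dicom_dir Directory containing exactly one PET series.
#' @return A `suv_image`; `provenance` records the conversion inputs.
#' @export
load_pet_suv <- function(dicom_dir) {
  files <- list.files(dicom_dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files))
    files <- list.files(dicom_dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no DICOM files found in ", dicom_dir)
  dss <- lapply(files, read_dicom_file)
  uids <- vapply(dss, function(d)
    if (is.null(d[["0020,000E"]])) NA_character_ else d[["0020,000E"]],
    "")
  if (length(unique(uids)) != 1)
    stop("mixed series in ", dicom_dir, ": ",
         paste(unique(uids), collapse = ", "))
  d1 <- dss[[1]]
  need <- c(weight = "0010,1030", units = "0054,1001",
            rows = "0028,0010", cols = "0028,0011",
            pixel_spacing = "0028,0030", position = "0020,0032",
            orientation = "0020,0037")
  rph <- d1[["0054,0016"]]
  missing_tags <- names(need)[vapply(need, function(t) is.null(d1[[t]]),
                                     TRUE)]
  dose <- if (!is.null(rph)) rph[[1]][["0018,1074"]] else NULL
  half <- if (!is.null(rph)) rph[[1]][["0018,1075"]] else NULL
  inj <- if (!is.null(rph)) rph[[1]][["0018,1072"]] else d1[["0018,1072"]]
  if (is.null(dose)) missing_tags <- c(missing_tags, "RadionuclideTotalDose")
  if (is.null(half)) missing_tags <- c(missing_tags, "RadionuclideHalfLife")
  if (is.null(inj))
    missing_tags <- c(missing_tags, "RadiopharmaceuticalStartTime")
  if (is.null(d1[["0008,0031"]])) missing_tags <- c(missing_tags,
                                                    "SeriesTime")
  if (length(missing_tags))
    stop("cannot compute SUV: missing tags ",
         paste(missing_tags, collapse = ", "))
  units <- d1[["0054,1001"]]
  if (units != "BQML")
    stop("cannot compute SUV: Units is ", units, ", expected BQML")

  iop <- d1[["0020,0037"]]
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  pos <- t(vapply(dss, function(d) d[["0020,0032"]], numeric(3)))
  ord <- order(pos %*% normal)
  dss <- dss[ord]; pos <- pos[ord, , drop = FALSE]
  nz <- length(dss)
  dz <- if (nz > 1) diff(sort(pos %*% normal))
        else if (!is.null(d1[["0018,0050"]])) d1[["0018,0050"]] else 1
  if (nz > 1 && (max(dz) - min(dz)) > 1e-3)
    stop("non-uniform slice spacing in ", dicom_dir)
  dz <- mean(dz)
  nr <- d1[["0028,0010"]]; nc <- d1[["0028,0011"]]
  ps <- d1[["0028,0030"]]           # (row spacing, column spacing)
  arr <- array(0, c(nc, nr, nz))
  for (k in seq_len(nz)) {
    dk <- dss[[k]]
    slope <- if (is.null(dk[["0028,1053"]])) 1 else dk[["0028,1053"]]
    inter <- if (is.null(dk[["0028,1052"]])) 0 else dk[["0028,1052"]]
    px <- dk[["7FE0,0010"]]
    if (is.null(px)) stop("missing PixelData in slice ", k)
    signed <- !is.null(dk[["0028,0103"]]) && dk[["0028,0103"]] == 1
    v <- readBin(px, "integer", n = nr * nc, size = 2, endian = "little",
                 signed = signed)
    arr[, , k] <- matrix(v, nrow = nc) * slope + inter
  }
  weight_g <- d1[["0010,1030"]] * 1000
  dc <- if (is.null(d1[["0054,1102"]])) "START" else d1[["0054,1102"]]
  elapsed <- .tm_seconds(d1[["0008,0031"]]) - .tm_seconds(inj)
  dose <- dose[1]; half <- half[1]
  decayed_dose <- if (identical(dc, "ADMIN")) dose
                  else dose * 2^(-elapsed / half)
  suv <- arr * weight_g / decayed_dose
  direction <- cbind(iop[1:3], iop[4:6], normal)
  suv_image(pmax(suv, 0), spacing = c(ps[2], ps[1], dz),
            origin = pos[1, ], direction = direction,
            provenance = list(source = "dicom", dir = dicom_dir,
                              weight_kg = weight_g / 1000, dose_bq = dose,
                              half_life_s = half, elapsed_s = elapsed,
                              decay_correction = dc, units = units))
}
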