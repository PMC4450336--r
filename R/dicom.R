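# Minimal DICOM support: explicit VR little endian only, the CT / RT-DOSE /
# RT-STRUCT attributes the pipeline needs. Readers are total on files
# produced by the writers below; clinical-grade generality (other transfer
# syntaxes, compressed pixel data, oblique orientations) is out of scope.

UID_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_ROOT <- "1.2.826.0.1.3680043.10.1453" # arbitrary private root

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

le_bytes <- function(x, nbytes) {
  x <- as.numeric(x)
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

from_le <- function(r) sum(as.numeric(r) * 256^(seq_along(r) - 1))

dcm_pad <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L) c(r, pad) else r
}

encode_value <- function(vr, value) {
  switch(vr,
    UI = dcm_pad(charToRaw(as.character(value)), as.raw(0)),
    US = do.call(c, lapply(as.integer(value), le_bytes, nbytes = 2L)),
    UL = do.call(c, lapply(as.numeric(value), le_bytes, nbytes = 4L)),
    OB = as.raw(value),
    OW = value, # pre-encoded raw
    SQ = value, # pre-encoded raw (items)
    dcm_pad(charToRaw(paste(as.character(value), collapse = "\\")))
  )
}

dcm_element <- function(group, element, vr, value) {
  body <- encode_value(vr, value)
  head <- c(le_bytes(group, 2L), le_bytes(element, 2L), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, raw(2L), le_bytes(length(body), 4L), body)
  } else {
    if (length(body) > 65534) stop("value too long for short-form VR")
    c(head, le_bytes(length(body), 2L), body)
  }
}

dcm_item <- function(content) {
  c(le_bytes(0xFFFE, 2L), le_bytes(0xE000, 2L), le_bytes(length(content), 4L),
    content)
}

fmt_ds <- function(x) {
  vapply(x, function(v) {
    s <- sprintf("%.10g", v)
    if (nchar(s) > 16) s <- sprintf("%.8g", v)
    s
  }, "")
}

new_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0(UID_ROOT, ".", as.integer(Sys.time()) %% 100000L, ".",
           sample.int(100000L, 1L), ".", counter)
  }
})

write_dicom_file <- function(path, sop_class, sop_instance, dataset_raw) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", c(0L, 1L)),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", UID_TS_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_element(0x0002, 0x0000, "UL", length(meta)), con)
  writeBin(meta, con)
  writeBin(dataset_raw, con)
  invisible(path)
}

# ---- parsing ----

# Parses elements from raw bytes; returns list(elements, next position).
# Each element: list(group, element, vr, value (raw), items (for SQ)).
parse_dataset <- function(bytes, pos, end) {
  out <- list()
  while (pos + 7 <= end) {
    group <- from_le(bytes[pos:(pos + 1)])
    element <- from_le(bytes[(pos + 2):(pos + 3)])
    if (group == 0xFFFE) break # item/sequence delimiter: caller handles
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt DICOM stream (only explicit VR little endian is supported)",
           call. = FALSE)
    if (vr %in% LONG_VRS) {
      len <- from_le(bytes[(pos + 8):(pos + 11)])
      pos <- pos + 12
    } else {
      len <- from_le(bytes[(pos + 6):(pos + 7)])
      pos <- pos + 8
    }
    el <- list(group = group, element = element, vr = vr)
    if (vr == "SQ") {
      res <- parse_items(bytes, pos, if (len == 0xFFFFFFFF) end else pos + len,
                         undefined = (len == 0xFFFFFFFF))
      el$items <- res$items
      pos <- res$pos
    } else {
      if (len == 0xFFFFFFFF) stop("undefined length outside SQ unsupported", call. = FALSE)
      el$value <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
    }
    out[[length(out) + 1L]] <- el
  }
  list(elements = out, pos = pos)
}

parse_items <- function(bytes, pos, end, undefined) {
  items <- list()
  while (pos + 7 <= end) {
    group <- from_le(bytes[pos:(pos + 1)])
    element <- from_le(bytes[(pos + 2):(pos + 3)])
    len <- from_le(bytes[(pos + 4):(pos + 7)])
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      stop("malformed sequence item", call. = FALSE)
    if (len == 0xFFFFFFFF) {
      res <- parse_dataset(bytes, pos, end)
      pos <- res$pos
      # skip item delimiter
      if (pos + 7 <= end && from_le(bytes[(pos + 2):(pos + 3)]) == 0xE00D)
        pos <- pos + 8
      items[[length(items) + 1L]] <- res$elements
    } else {
      res <- parse_dataset(bytes, pos, pos + len)
      items[[length(items) + 1L]] <- res$elements
      pos <- pos + len
    }
  }
  list(items = items, pos = pos)
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("not a DICOM part-10 file: %s", path), call. = FALSE)
  # file meta group is always explicit LE
  res <- parse_meta_then_data(bytes)
  res
}

parse_meta_then_data <- function(bytes) {
  pos <- 133
  if (from_le(bytes[pos:(pos + 1)]) != 0x0002 ||
      from_le(bytes[(pos + 2):(pos + 3)]) != 0x0000 ||
      rawToChar(bytes[(pos + 4):(pos + 5)]) != "UL")
    stop("missing file meta group length", call. = FALSE)
  meta_len <- from_le(bytes[(pos + 8):(pos + 11)])
  meta_end <- pos + 12 + meta_len
  meta <- parse_dataset(bytes, pos + 12, meta_end)$elements
  ts <- el_string(find_el(meta, 0x0002, 0x0010))
  if (!identical(ts, UID_TS_EXPLICIT_LE))
    stop(sprintf("unsupported transfer syntax: %s", ts), call. = FALSE)
  data <- parse_dataset(bytes, meta_end, length(bytes))$elements
  list(meta = meta, data = data)
}

find_el <- function(elements, group, element) {
  for (el in elements)
    if (el$group == group && el$element == element) return(el)
  NULL
}

el_string <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$value[el$value != as.raw(0)] # strip UI null padding
  trimws(rawToChar(v))
}

el_numbers <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(el_string(el), "\\", fixed = TRUE)[[1]])
}

el_us <- function(el) {
  if (is.null(el)) return(NULL)
  n <- length(el$value) / 2
  vapply(seq_len(n), function(i) from_le(el$value[(2 * i - 1):(2 * i)]), 0)
}
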