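# Minimal DICOM writer used to build tiny single-frame fixtures in code.
# Little-endian; explicit or implicit VR for the dataset group.

write_test_dicom <- function(path, pixels, bits_allocated = 16L,
                             bits_stored = bits_allocated,
                             explicit = TRUE, n_frames = NULL,
                             samples = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")

  elem_short <- function(group, el, vr, payload_writer, len) {
    u16(group); u16(el)
    writeChar(vr, con, nchars = 2L, eos = NULL)
    u16(len)
    payload_writer()
  }
  elem_implicit <- function(group, el, payload_writer, len) {
    u16(group); u16(el); u32(len)
    payload_writer()
  }
  elem_long <- function(group, el, vr, payload_writer, len) {
    u16(group); u16(el)
    writeChar(vr, con, nchars = 2L, eos = NULL)
    writeBin(as.raw(c(0, 0)), con)
    u32(len)
    payload_writer()
  }

  writeBin(raw(128L), con)
  writeChar("DICM", con, nchars = 4L, eos = NULL)

  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  ts_pad <- if (nchar(ts) %% 2 == 1) paste0(ts, " ") else ts
  elem_short(0x0002L, 0x0010L, "UI",
             function() writeChar(ts_pad, con, nchars = nchar(ts_pad),
                                  eos = NULL),
             nchar(ts_pad))

  us_elem <- function(group, el, value) {
    if (explicit) elem_short(group, el, "US", function() u16(value), 2L)
    else elem_implicit(group, el, function() u16(value), 2L)
  }
  us_elem(0x0028L, 0x0002L, samples)
  if (!is.null(n_frames)) {
    s <- as.character(n_frames)
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    wr <- function() writeChar(s, con, nchars = nchar(s), eos = NULL)
    if (explicit) elem_short(0x0028L, 0x0008L, "IS", wr, nchar(s))
    else elem_implicit(0x0028L, 0x0008L, wr, nchar(s))
  }
  us_elem(0x0028L, 0x0010L, nrow(pixels))
  us_elem(0x0028L, 0x0011L, ncol(pixels))
  us_elem(0x0028L, 0x0100L, bits_allocated)
  us_elem(0x0028L, 0x0101L, bits_stored)
  us_elem(0x0028L, 0x0103L, 0L)

  v <- as.integer(t(pixels))                    # row-major pixel order
  if (bits_allocated == 8L) {
    wr <- function() writeBin(as.raw(v), con)
    len <- length(v)
  } else {
    wr <- function() u16(v)
    len <- 2L * length(v)
  }
  if (explicit) elem_long(0x7FE0L, 0x0010L, "OW", wr, len)
  else elem_implicit(0x7FE0L, 0x0010L, wr, len)
  invisible(path)
}
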