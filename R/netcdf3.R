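# Minimal NetCDF-3 "classic" (CDF-1/CDF-2) binary reader and writer.
#
# Covers the subset needed for CF-style gridded daily data: named dimensions,
# fixed-size and record variables, numeric/char variables and attributes,
# big-endian encoding, 4-byte alignment.  The writer emits CDF-1 files with
# fixed dimensions only; the reader additionally understands the unlimited
# (record) dimension and CDF-2 64-bit offsets so externally produced files
# can be ingested.

NC3_TAG_DIM <- 10L   # NC_DIMENSION
NC3_TAG_VAR <- 11L   # NC_VARIABLE
NC3_TAG_ATT <- 12L   # NC_ATTRIBUTE

nc3_type_size <- c(1L, 1L, 2L, 4L, 4L, 8L)  # byte, char, short, int, float, double

nc3_type_id <- function(type) {
  switch(type,
    byte = 1L, char = 2L, short = 3L, int = 4L, float = 5L, double = 6L,
    stop("unknown NetCDF type: ", type)
  )
}

# ---- writer ---------------------------------------------------------------

nc3_pad4 <- function(n) as.integer(ceiling(n / 4) * 4)

nc3_write_name <- function(con, name) {
  bytes <- charToRaw(enc2utf8(name))
  writeBin(length(bytes), con, size = 4L, endian = "big")
  writeBin(bytes, con)
  pad <- nc3_pad4(length(bytes)) - length(bytes)
  if (pad > 0) writeBin(raw(pad), con)
}

nc3_write_values <- function(con, type, values) {
  if (type == "char") {
    bytes <- charToRaw(paste0(values, collapse = ""))
    writeBin(bytes, con)
    n <- length(bytes)
  } else if (type %in% c("int", "short", "byte")) {
    sz <- nc3_type_size[nc3_type_id(type)]
    writeBin(as.integer(values), con, size = sz, endian = "big")
    n <- length(values) * sz
  } else {
    sz <- nc3_type_size[nc3_type_id(type)]
    writeBin(as.double(values), con, size = sz, endian = "big")
    n <- length(values) * sz
  }
  pad <- nc3_pad4(n) - n
  if (pad > 0) writeBin(raw(pad), con)
}

nc3_att_type <- function(value) {
  if (is.character(value)) "char" else if (is.integer(value)) "int" else "double"
}

nc3_write_att_list <- function(con, atts) {
  if (length(atts) == 0L) {
    writeBin(c(0L, 0L), con, size = 4L, endian = "big")
    return(invisible())
  }
  writeBin(c(NC3_TAG_ATT, length(atts)), con, size = 4L, endian = "big")
  for (nm in names(atts)) {
    val <- atts[[nm]]
    type <- nc3_att_type(val)
    nc3_write_name(con, nm)
    writeBin(nc3_type_id(type), con, size = 4L, endian = "big")
    nelems <- if (type == "char") nchar(paste0(val, collapse = ""), type = "bytes") else length(val)
    writeBin(as.integer(nelems), con, size = 4L, endian = "big")
    nc3_write_values(con, type, val)
  }
  invisible()
}

nc3_header_raw <- function(dims, vars, gatts, begins) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("CDF"), con)
  writeBin(as.raw(1L), con)                       # CDF-1, 32-bit offsets
  writeBin(0L, con, size = 4L, endian = "big")    # numrecs (no record dim)
  if (length(dims) == 0L) {
    writeBin(c(0L, 0L), con, size = 4L, endian = "big")
  } else {
    writeBin(c(NC3_TAG_DIM, length(dims)), con, size = 4L, endian = "big")
    for (nm in names(dims)) {
      nc3_write_name(con, nm)
      writeBin(as.integer(dims[[nm]]), con, size = 4L, endian = "big")
    }
  }
  nc3_write_att_list(con, gatts)
  if (length(vars) == 0L) {
    writeBin(c(0L, 0L), con, size = 4L, endian = "big")
  } else {
    writeBin(c(NC3_TAG_VAR, length(vars)), con, size = 4L, endian = "big")
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      nc3_write_name(con, v$name)
      dimids <- match(v$dims, names(dims)) - 1L
      writeBin(length(dimids), con, size = 4L, endian = "big")
      if (length(dimids) > 0) writeBin(dimids, con, size = 4L, endian = "big")
      nc3_write_att_list(con, v$atts %||% list())
      writeBin(nc3_type_id(v$type), con, size = 4L, endian = "big")
      nelem <- prod(vapply(v$dims, function(d) dims[[d]], numeric(1)))
      vsize <- nc3_pad4(nelem * nc3_type_size[nc3_type_id(v$type)])
      writeBin(as.integer(vsize), con, size = 4L, endian = "big")
      writeBin(as.integer(begins[i]), con, size = 4L, endian = "big")
    }
  }
  rawConnectionValue(con)
}

#' Write a NetCDF-3 classic file (fixed dimensions only)
#'
#' @param path output file path.
#' @param dims named list of dimension lengths.
#' @param vars list of variable descriptors: `name`, `dims` (character vector,
#'   slowest-varying first as in the NetCDF header), `type`, `data` (vector in
#'   NetCDF order, last dimension varying fastest), optional `atts`.
#' @param gatts named list of global attributes.
#' @keywords internal
nc3_write <- function(path, dims, vars, gatts = list()) {
  for (v in vars) {
    nelem <- prod(vapply(v$dims, function(d) dims[[d]], numeric(1)))
    if (v$type != "char" && length(v$data) != nelem) {
      stop("variable ", v$name, ": data length ", length(v$data),
           " does not match dimensions (", nelem, ")")
    }
  }
  hdr0 <- nc3_header_raw(dims, vars, gatts, begins = rep(0L, length(vars)))
  vsizes <- vapply(vars, function(v) {
    nelem <- prod(vapply(v$dims, function(d) dims[[d]], numeric(1)))
    nc3_pad4(nelem * nc3_type_size[nc3_type_id(v$type)])
  }, integer(1))
  begins <- length(hdr0) + c(0L, cumsum(vsizes))[seq_along(vars)]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(nc3_header_raw(dims, vars, gatts, begins), con)
  for (v in vars) nc3_write_values(con, v$type, v$data)
  invisible(path)
}

# ---- reader ---------------------------------------------------------------

nc3_read_int <- function(con) readBin(con, integer(), size = 4L, endian = "big")

nc3_read_name <- function(con) {
  n <- nc3_read_int(con)
  bytes <- readBin(con, raw(), n = n)
  pad <- nc3_pad4(n) - n
  if (pad > 0) readBin(con, raw(), n = pad)
  rawToChar(bytes)
}

nc3_read_typed <- function(con, type_id, nelems) {
  sz <- nc3_type_size[type_id]
  vals <- switch(type_id,
    readBin(con, integer(), n = nelems, size = 1L, signed = TRUE),        # byte
    rawToChar(readBin(con, raw(), n = nelems)),                           # char
    readBin(con, integer(), n = nelems, size = 2L, endian = "big"),       # short
    readBin(con, integer(), n = nelems, size = 4L, endian = "big"),       # int
    readBin(con, double(),  n = nelems, size = 4L, endian = "big"),       # float
    readBin(con, double(),  n = nelems, size = 8L, endian = "big")        # double
  )
  pad <- nc3_pad4(nelems * sz) - nelems * sz
  if (pad > 0) readBin(con, raw(), n = pad)
  vals
}

nc3_read_att_list <- function(con) {
  tag <- nc3_read_int(con)
  n <- nc3_read_int(con)
  if (tag == 0L && n == 0L) return(list())
  if (tag != NC3_TAG_ATT) format_error("malformed NetCDF header: bad attribute-list tag")
  atts <- list()
  for (i in seq_len(n)) {
    nm <- nc3_read_name(con)
    type_id <- nc3_read_int(con)
    nelems <- nc3_read_int(con)
    atts[[nm]] <- nc3_read_typed(con, type_id, nelems)
  }
  atts
}

#' Read a NetCDF-3 classic file
#'
#' Returns dimensions, global attributes, and per-variable data (as vectors in
#' NetCDF order) with attributes.  Supports CDF-1 and CDF-2 files including an
#' unlimited (record) dimension.
#' @keywords internal
nc3_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 4L)
  if (!identical(rawToChar(magic[1:3]), "CDF") || !as.integer(magic[4]) %in% c(1L, 2L)) {
    format_error(sprintf("not a NetCDF-3 classic file: %s", path))
  }
  offset64 <- as.integer(magic[4]) == 2L
  read_offset <- function() {
    if (offset64) {
      hi <- nc3_read_int(con); lo <- nc3_read_int(con)
      hi * 2^32 + (lo %% 2^32)
    } else nc3_read_int(con)
  }
  numrecs <- nc3_read_int(con)

  tag <- nc3_read_int(con); n <- nc3_read_int(con)
  dims <- list(); rec_dim <- NA_integer_
  if (tag == NC3_TAG_DIM) {
    for (i in seq_len(n)) {
      nm <- nc3_read_name(con)
      len <- nc3_read_int(con)
      if (len == 0L) rec_dim <- i
      dims[[nm]] <- len
    }
  } else if (!(tag == 0L && n == 0L)) {
    format_error("malformed NetCDF header: bad dimension-list tag")
  }

  gatts <- nc3_read_att_list(con)

  tag <- nc3_read_int(con); n <- nc3_read_int(con)
  vars <- list()
  if (tag == NC3_TAG_VAR) {
    for (i in seq_len(n)) {
      nm <- nc3_read_name(con)
      ndims <- nc3_read_int(con)
      dimids <- if (ndims > 0) readBin(con, integer(), n = ndims, size = 4L, endian = "big") + 1L else integer(0)
      atts <- nc3_read_att_list(con)
      type_id <- nc3_read_int(con)
      vsize <- nc3_read_int(con)
      begin <- read_offset()
      vars[[nm]] <- list(
        name = nm, dimids = dimids, dims = names(dims)[dimids],
        type_id = type_id, vsize = vsize, begin = begin,
        atts = atts, is_record = !is.na(rec_dim) && rec_dim %in% dimids
      )
    }
  } else if (!(tag == 0L && n == 0L)) {
    format_error("malformed NetCDF header: bad variable-list tag")
  }

  rec_vars <- Filter(function(v) v$is_record, vars)
  recsize <- sum(vapply(rec_vars, function(v) v$vsize, numeric(1)))

  for (nm in names(vars)) {
    v <- vars[[nm]]
    lens <- unlist(dims[v$dims], use.names = FALSE)
    if (v$is_record) {
      per_rec <- prod(lens[v$dimids != rec_dim])  # prod(numeric(0)) == 1
      vals_type <- if (v$type_id %in% c(5L, 6L)) double() else integer()
      acc <- vector(mode = typeof(vals_type), length = 0L)
      for (r in seq_len(max(numrecs, 0L))) {
        seek(con, where = v$begin + (r - 1) * recsize)
        acc <- c(acc, nc3_read_typed(con, v$type_id, per_rec))
      }
      vars[[nm]]$data <- acc
      vars[[nm]]$shape <- c(numrecs, lens[which(v$dimids != rec_dim)])
    } else {
      seek(con, where = v$begin)
      nelem <- if (length(lens) == 0) 1L else prod(lens)
      vars[[nm]]$data <- nc3_read_typed(con, v$type_id, nelem)
      vars[[nm]]$shape <- if (length(lens) == 0) 1L else lens
    }
  }
  dims_out <- dims
  if (!is.na(rec_dim)) dims_out[[rec_dim]] <- numrecs
  list(dims = dims_out, gatts = gatts, vars = vars)
}
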