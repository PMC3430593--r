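# MDL connection-table I/O. V2000 and V3000 are both read; V3000 is written
# whenever enhanced stereo groups are present (V2000 cannot express them).
# Atom indices are 0-based internally and 1-based on disk per the MDL spec.

.wedge_from_v2000 <- c("0" = "none", "1" = "up", "4" = "either", "6" = "down")
.wedge_to_v2000   <- c(none = 0L, up = 1L, either = 4L, down = 6L)
.wedge_from_v3000 <- c("0" = "none", "1" = "up", "2" = "either", "3" = "down")
.wedge_to_v3000   <- c(none = 0L, up = 1L, either = 2L, down = 3L)
.chg_from_v2000   <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "4" = 0L,
                       "5" = -1L, "6" = -2L, "7" = -3L)

#' Read an MDL molfile
#'
#' Accepts V2000 and V3000 connection tables; V3000 enhanced stereo
#' collections (`STEABS`, `STERAC<n>`, `STEREL<n>`) become
#' [stereo_group()] annotations. A molfile with zero atoms is returned as a
#' No Structure record.
#'
#' @param text Molfile content as a single string or character vector of
#'   lines.
#' @return A [structure_record()].
#' @export
read_molfile <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 4L)
    stop("molfile too short (", length(lines), " lines)", call. = FALSE)
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) read_v3000(lines)
  else if (grepl("V2000", counts, fixed = TRUE)) read_v2000(lines)
  else stop("line 4: neither a V2000 nor a V3000 counts line: ",
            trimws(counts), call. = FALSE)
}

read_v2000 <- function(lines) {
  na <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nb <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(na) || is.na(nb))
    stop("line 4: malformed V2000 counts line", call. = FALSE)
  if (na == 0L) return(structure_record(no_structure = TRUE))
  if (length(lines) < 4L + na + nb)
    stop("molfile truncated: counts promise ", na, " atoms / ", nb,
         " bonds", call. = FALSE)
  at <- lines[5:(4 + na)]
  atoms <- data.frame(
    elem = trimws(substr(at, 32, 34)),
    charge = unname(.chg_from_v2000[as.character(
      suppressWarnings(as.integer(substr(at, 37, 39))))]),
    isotope = NA_integer_,
    hcount = NA_integer_,
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    stringsAsFactors = FALSE)
  atoms$charge[is.na(atoms$charge)] <- 0L
  bonds <- empty_bonds()
  if (nb > 0L) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)) - 1L,
      j = as.integer(substr(bl, 4, 6)) - 1L,
      order = as.integer(substr(bl, 7, 9)),
      wedge = unname(.wedge_from_v2000[trimws(substr(bl, 10, 12))]),
      stringsAsFactors = FALSE)
    bonds$wedge[is.na(bonds$wedge)] <- "none"
  }
  # property block: M  CHG / M  ISO override the atom block
  for (ln in lines[-seq_len(4L + na + nb)]) {
    if (grepl("^M  END", ln)) break
    if (grepl("^M  (CHG|ISO)", ln)) {
      f <- scan(text = substr(ln, 7, nchar(ln)), what = integer(),
                quiet = TRUE)
      cnt <- f[1]
      if (grepl("CHG", ln)) atoms$charge[] <- 0L  # CHG resets all charges
      for (p in seq_len(cnt)) {
        idx <- f[2 * p]; val <- f[2 * p + 1]
        if (grepl("CHG", ln)) atoms$charge[idx] <- as.integer(val)
        else atoms$isotope[idx] <- as.integer(val)
      }
    }
  }
  structure_record(atoms, bonds)
}

read_v3000 <- function(lines) {
  v30 <- sub("^M  V30 ", "", lines[grepl("^M  V30 ", lines)])
  # join continuation lines (trailing "-")
  out <- character(0)
  carry <- ""
  for (ln in v30) {
    if (grepl("-$", ln)) carry <- paste0(carry, sub("-$", "", ln))
    else { out <- c(out, paste0(carry, ln)); carry <- "" }
  }
  v30 <- out
  sect <- function(name) {
    b <- which(v30 == paste("BEGIN", name))
    e <- which(v30 == paste("END", name))
    if (!length(b) || !length(e)) return(character(0))
    if (e[1] - b[1] < 2) return(character(0))
    v30[(b[1] + 1):(e[1] - 1)]
  }
  cl <- v30[grepl("^COUNTS ", v30)]
  if (!length(cl)) stop("V3000 block lacks a COUNTS line", call. = FALSE)
  na <- as.integer(strsplit(trimws(cl[1]), "\\s+")[[1]][2])
  if (na == 0L) return(structure_record(no_structure = TRUE))
  kv <- function(toks, key, default = NA) {
    hit <- grep(paste0("^", key, "="), toks, value = TRUE)
    if (!length(hit)) default else sub(paste0("^", key, "="), "", hit[1])
  }
  atl <- sect("ATOM")
  atoms <- empty_atoms()
  idx_map <- integer(0)
  for (ln in atl) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    idx_map <- c(idx_map, as.integer(toks[1]))
    atoms <- rbind(atoms, data.frame(
      elem = toks[2],
      charge = as.integer(kv(toks, "CHG", "0")),
      isotope = { m <- kv(toks, "MASS", NA); if (is.na(m)) NA_integer_ else as.integer(m) },
      hcount = NA_integer_,
      x = as.numeric(toks[3]), y = as.numeric(toks[4]),
      stringsAsFactors = FALSE))
  }
  remap <- function(file_idx) match(file_idx, idx_map) - 1L
  bl <- sect("BOND")
  bonds <- empty_bonds()
  for (ln in bl) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    w <- .wedge_from_v3000[kv(toks, "CFG", "0")]
    bonds <- rbind(bonds, data.frame(
      i = remap(as.integer(toks[3])), j = remap(as.integer(toks[4])),
      order = as.integer(toks[2]),
      wedge = unname(ifelse(is.na(w), "none", w)),
      stringsAsFactors = FALSE))
  }
  groups <- list()
  for (ln in sect("COLLECTION")) {
    m <- regmatches(ln, regexec(
      "MDLV30/(STEABS|STERAC([0-9]+)|STEREL([0-9]+)) +ATOMS=\\(([^)]*)\\)", ln))[[1]]
    if (!length(m)) next
    ids <- scan(text = m[5], what = integer(), quiet = TRUE)[-1]
    kind <- if (grepl("^STEABS", m[2])) "absolute"
            else if (grepl("^STERAC", m[2])) "and" else "or"
    ordinal <- if (kind == "absolute") 1L
               else as.integer(if (kind == "and") m[3] else m[4])
    groups <- c(groups, list(stereo_group(kind, remap(ids), ordinal)))
  }
  structure_record(atoms, bonds, stereo_groups = groups)
}

fmt_coord <- function(x) formatC(round(x, 4), format = "f", digits = 4, width = 10)

#' Write a structure as an MDL molfile
#'
#' Emits V2000 by default and V3000 whenever the record carries stereo
#' groups (which V2000 cannot express) or when `version = "V3000"` is
#' forced. The header carries no timestamp so output is byte-stable.
#'
#' @param s A [structure_record()].
#' @param title Molfile title line.
#' @param version `"auto"`, `"V2000"`, or `"V3000"`.
#' @return Molfile text (single string, newline-terminated).
#' @export
write_molfile <- function(s, title = "", version = c("auto", "V2000", "V3000")) {
  version <- match.arg(version)
  if (version == "auto")
    version <- if (length(s$stereo_groups)) "V3000" else "V2000"
  if (version == "V2000" && length(s$stereo_groups))
    stop("stereo groups cannot be expressed in V2000", call. = FALSE)
  header <- c(substr(title, 1, 80), "  ucdreg            2D", "")
  na <- nrow(s$atoms); nb <- nrow(s$bonds)
  if (version == "V2000") {
    counts <- sprintf("%3d%3d  0  0  1  0  0  0  0  0999 V2000", na, nb)
    at <- sprintf("%s%s    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                  fmt_coord(s$atoms$x), fmt_coord(s$atoms$y), s$atoms$elem)
    bl <- if (nb) sprintf("%3d%3d%3d%3d  0  0  0",
                          s$bonds$i + 1L, s$bonds$j + 1L, s$bonds$order,
                          .wedge_to_v2000[s$bonds$wedge]) else character(0)
    props <- character(0)
    chg <- which(s$atoms$charge != 0L)
    if (length(chg)) {
      # M CHG lines carry at most 8 pairs each
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        props <- c(props, paste0("M  CHG", sprintf("%3d", length(grp)),
          paste0(sprintf("%4d%4d", grp, s$atoms$charge[grp]), collapse = "")))
      }
    }
    iso <- which(!is.na(s$atoms$isotope))
    if (length(iso)) {
      props <- c(props, paste0("M  ISO", sprintf("%3d", length(iso)),
        paste0(sprintf("%4d%4d", iso, s$atoms$isotope[iso]), collapse = "")))
    }
    return(paste0(paste(c(header, counts, at, bl, props, "M  END"),
                        collapse = "\n"), "\n"))
  }
  # V3000
  ln <- c(sprintf("M  V30 COUNTS %d %d 0 0 1", na, nb), "M  V30 BEGIN ATOM")
  for (k in seq_len(na)) {
    extra <- ""
    if (s$atoms$charge[k] != 0L) extra <- paste0(extra, " CHG=", s$atoms$charge[k])
    if (!is.na(s$atoms$isotope[k])) extra <- paste0(extra, " MASS=", s$atoms$isotope[k])
    ln <- c(ln, sprintf("M  V30 %d %s %.4f %.4f 0 0%s", k, s$atoms$elem[k],
                        round(s$atoms$x[k], 4), round(s$atoms$y[k], 4), extra))
  }
  ln <- c(ln, "M  V30 END ATOM", "M  V30 BEGIN BOND")
  for (k in seq_len(nb)) {
    cfg <- .wedge_to_v3000[[s$bonds$wedge[k]]]
    ln <- c(ln, sprintf("M  V30 %d %d %d %d%s", k, s$bonds$order[k],
                        s$bonds$i[k] + 1L, s$bonds$j[k] + 1L,
                        if (cfg != 0L) paste0(" CFG=", cfg) else ""))
  }
  ln <- c(ln, "M  V30 END BOND")
  if (length(s$stereo_groups)) {
    ln <- c(ln, "M  V30 BEGIN COLLECTION")
    for (g in s$stereo_groups) {
      tag <- switch(g$kind, absolute = "STEABS",
                    and = paste0("STERAC", g$ordinal),
                    or = paste0("STEREL", g$ordinal))
      ln <- c(ln, sprintf("M  V30 MDLV30/%s ATOMS=(%d %s)", tag,
                          length(g$atoms), paste(g$atoms + 1L, collapse = " ")))
    }
    ln <- c(ln, "M  V30 END COLLECTION")
  }
  paste0(paste(c(substr(title, 1, 80), "  ucdreg            2D", "",
                 "  0  0  0  0  0  0  0  0  0  0999 V3000",
                 "M  V30 BEGIN CTAB", ln, "M  V30 END CTAB", "M  END"),
               collapse = "\n"), "\n")
}

# ---- SDF --------------------------------------------------------------------

#' Read a structure-data (SDF) file
#'
#' @param path File path, or the file's content via `text =`.
#' @param text Optional SDF content as a single string (overrides `path`).
#' @return A list of records, each `list(structure =, data = named character
#'   vector, title =)`. A record whose molfile fails to parse is returned
#'   with `structure = NULL` and the parse error message in `error`.
#' @export
read_sdf <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, utils::head(lines, -1) == "$$$$")))
  out <- list()
  for (rl in recs) {
    if (length(rl) && rl[length(rl)] == "$$$$") rl <- rl[-length(rl)]
    if (!length(rl) || all(!nzchar(trimws(rl)))) next
    endct <- grep("^M  END", rl)
    molpart <- if (length(endct)) rl[1:endct[1]] else rl
    datapart <- if (length(endct) && endct[1] < length(rl))
      rl[(endct[1] + 1):length(rl)] else character(0)
    fields <- character(0)
    k <- 1
    while (k <= length(datapart)) {
      m <- regmatches(datapart[k], regexec("^> *<([^>]*)>", datapart[k]))[[1]]
      if (length(m)) {
        vals <- character(0)
        k <- k + 1
        while (k <= length(datapart) && nzchar(datapart[k]) &&
               !grepl("^>", datapart[k])) {
          vals <- c(vals, datapart[k]); k <- k + 1
        }
        fields[m[2]] <- paste(vals, collapse = "\n")
      } else k <- k + 1
    }
    rec <- list(title = trimws(molpart[1]), data = fields)
    rec$structure <- tryCatch(read_molfile(molpart), error = function(e) NULL)
    if (is.null(rec$structure)) rec$error <- conditionMessage(
      tryCatch(read_molfile(molpart), error = function(e) e))
    out <- c(out, list(rec))
  }
  out
}

#' Write records to an SDF file
#'
#' @param records List of `list(structure =, data =, title =)` entries.
#' @param path Output path; when `NULL` the SDF text is returned instead.
#' @param version Molfile version passed to [write_molfile()].
#' @return Invisibly, the number of records written (or the SDF text when
#'   `path` is `NULL`).
#' @export
write_sdf <- function(records, path = NULL, version = "auto") {
  chunks <- vapply(records, function(rec) {
    mol <- write_molfile(rec$structure, title = rec$title %||% "",
                         version = version)
    dat <- ""
    if (length(rec$data)) {
      dat <- paste0(paste0("> <", names(rec$data), ">\n", rec$data, "\n",
                           collapse = "\n"), "\n")
    }
    paste0(mol, dat, "$$$$\n")
  }, "")
  txt <- paste(chunks, collapse = "")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(length(records))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
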