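# OpenBabel bridge. Format interconversion (SMILES <-> molfile, InChI,
# canonical SMILES) is delegated to Open Babel via ChemmineOB and the obabel
# executable; everything identity-bearing (stereo groups, the uniqueness
# key) stays in this package.

.ob_cache <- new.env(parent = emptyenv())

ob_convert <- function(from, to, text, gen2d = FALSE) {
  tryCatch({
    if (gen2d)
      ChemmineOB::convertFormat(from, to, text,
                                options = data.frame(names = "gen2d",
                                                     args = ""))
    else
      ChemmineOB::convertFormat(from, to, text)
  }, error = function(e) stop("Open Babel conversion ", from, "->", to,
                              " failed: ", conditionMessage(e),
                              call. = FALSE))
}

# structure -> plain V2000 text for consumption by Open Babel (stereo
# groups stripped; wedges kept so tetrahedral stereo is perceived)
to_plain_v2000 <- function(s, title = "") {
  plain <- s
  plain$stereo_groups <- list()
  write_molfile(plain, title = title, version = "V2000")
}

#' Parse a chemical structure from SMILES or molfile text
#'
#' The dialect is auto-detected: multi-line input (or input containing a
#' `V2000`/`V3000` counts line) is read as a molfile, anything else as
#' SMILES. SMILES input is laid out in 2D (with stereo wedges where the
#' SMILES defines configuration) so that downstream wedge-based rules apply
#' uniformly.
#'
#' @param text Structure text.
#' @param dialect `"auto"`, `"smiles"`, or `"molfile"`.
#' @return A [structure_record()].
#' @examples
#' \donttest{
#' parse_structure("N#CCC(=O)O")   # 2-cyanoacetic acid
#' }
#' @export
parse_structure <- function(text, dialect = c("auto", "smiles", "molfile")) {
  dialect <- match.arg(dialect)
  if (!is.character(text) || !length(text) || !any(nzchar(trimws(text))))
    stop("empty structure input", call. = FALSE)
  is_mol <- length(text) > 1L || grepl("\n", text, fixed = TRUE) ||
    grepl("V[23]000", text)
  if (dialect == "molfile" || (dialect == "auto" && is_mol))
    return(read_molfile(text))
  smi <- trimws(text[1])
  mol <- ob_convert("SMI", "MOL", smi, gen2d = TRUE)
  if (!nzchar(trimws(mol)) || !grepl("V2000", mol))
    stop("SMILES parse failure: '", smi, "'", call. = FALSE)
  s <- read_molfile(mol)
  if (s$no_structure)
    stop("SMILES parse failure (no atoms): '", smi, "'", call. = FALSE)
  s
}

#' Canonical SMILES of a structure
#'
#' Open Babel canonical SMILES of the drawn (wedge-perceived) structure.
#' Enhanced stereo groups are not expressible in SMILES and are therefore
#' not encoded here; the registration key ([canonical_keys()]) carries them.
#'
#' @param s A [structure_record()].
#' @return SMILES string.
#' @export
structure_to_smiles <- function(s) {
  if (s$no_structure) stop("No Structure record has no SMILES", call. = FALSE)
  out <- ob_convert("MOL", "CAN", to_plain_v2000(s))
  trimws(sub("\t.*$", "", out))
}

# standard InChI (+ auxiliary info) of a structure; cached on molfile text.
# AuxInfo supplies the InChI canonical numbering (/N: layer) used to
# serialize stereo groups order-independently.
structure_to_inchi <- function(s, with_aux = TRUE) {
  mol <- to_plain_v2000(s)
  key <- paste0(if (with_aux) "a:" else "p:", mol)
  hit <- .ob_cache[[key]]
  if (!is.null(hit)) return(hit)
  tmp <- tempfile(fileext = ".mol")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(mol, tmp, sep = "")
  args <- c(shQuote(tmp), "-oinchi")
  if (with_aux) args <- c(args, "-xa")
  out <- suppressWarnings(system2("obabel", args, stdout = TRUE,
                                  stderr = FALSE))
  inchi <- grep("^InChI=", out, value = TRUE)
  if (!length(inchi))
    stop("InChI generation failed for structure", call. = FALSE)
  res <- list(inchi = inchi[1],
              auxinfo = grep("^AuxInfo=", out, value = TRUE)[1])
  .ob_cache[[key]] <- res
  res
}

# /N: layer of AuxInfo -> integer vector: canonical position k holds the
# 1-based original atom number of InChI canonical atom k
auxinfo_numbering <- function(auxinfo) {
  m <- regmatches(auxinfo, regexec("/N:([0-9,;]+)", auxinfo))[[1]]
  if (!length(m)) return(integer(0))
  scan(text = gsub(";", ",", m[2]), what = integer(), sep = ",", quiet = TRUE)
}

# parse the tetrahedral layer of an InChI: named vector parity("+"/"-") by
# InChI canonical atom number; centers printed with "?" are dropped
inchi_t_layer <- function(inchi) {
  m <- regmatches(inchi, regexec("/t([0-9+?,-]+)", inchi))[[1]]
  if (!length(m)) return(character(0))
  entries <- strsplit(m[2], ",", fixed = TRUE)[[1]]
  num <- sub("[+?-]$", "", entries)
  par <- substr(entries, nchar(entries), nchar(entries))
  keep <- par %in% c("+", "-")
  stats::setNames(par[keep], num[keep])
}

# /m layer (enantiomer flag): "0", "1" or NA
inchi_m_layer <- function(inchi) {
  m <- regmatches(inchi, regexec("/m([01])", inchi))[[1]]
  if (!length(m)) NA_character_ else m[2]
}

# InChI with the tetrahedral stereo layers (/t /m /s) removed: the
# tautomer-insensitive skeleton identity (mobile-H canonicalization keeps
# tautomers together; /b cis-trans stays, it is not tautomeric)
strip_stereo_layers <- function(inchi) {
  gsub("/[tms][^/]*", "", inchi)
}
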