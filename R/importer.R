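# Bulk SDF migration: every record runs through the same
# parse -> standardize -> validate -> submit -> decide path as manual
# entry, so bulk and manual registration have identical uniqueness
# semantics. Records with auto-fixed issues register with warnings;
# records with validation errors are rejected and the import continues.

#' Default SDF data-field to batch-metadata mapping
#'
#' Names are SDF tags, values are metadata fields. Unmapped tags are kept
#' verbatim under their own names.
#'
#' @return Named character vector.
#' @export
default_field_map <- function() {
  c(PROJECT = "project", SCIENTIST = "scientist",
    NOTEBOOK_REF = "notebook_ref", SOURCE = "source",
    COMMON_NAME = "common_name", EXPERIMENTAL_MW = "experimental_mw",
    SALT = "salt", SALT_COEFF = "salt_coeff", HYDRATE = "hydrate",
    MIXTURE_RATIO = "mixture_ratio", NO_STRUCTURE = "no_structure")
}

map_record_metadata <- function(data, field_map, schema) {
  meta <- list()
  for (tag in names(data)) {
    key <- if (tag %in% names(field_map)) field_map[[tag]] else tag
    meta[[key]] <- data[[tag]]
  }
  meta
}

#' Bulk-import an SDF file
#'
#' Reads the file record by record; each record is parsed, standardized,
#' validated and submitted with its mapped metadata. With
#' `auto_approve = TRUE` (registrar only) every submission immediately
#' flows through [decide_submission()], giving bulk import the exact
#' uniqueness semantics of manual registration. Malformed or invalid
#' records are rejected individually and the import continues.
#'
#' Composition directives travel in data fields: `SALT` / `SALT_COEFF`
#' (semicolon-separated parallel lists), `HYDRATE`, `MIXTURE_RATIO`
#' (e.g. `"1:1"`), `NO_STRUCTURE`.
#'
#' @param reg A [ucd_registry()].
#' @param path SDF file path.
#' @param actor Acting user (registrar when `auto_approve`, else
#'   submitter).
#' @param auto_approve Approve each submission immediately.
#' @param field_map SDF tag to metadata field mapping
#'   ([default_field_map()]).
#' @return A `ucd_import_report`: counts plus a per-record disposition
#'   table (`record`, `outcome` in registered / registered_with_warnings /
#'   rejected / submitted, `rules`, `molecule_code`, `substance_code`,
#'   `batch_code`, `message`).
#' @export
import_sdf <- function(reg, path, actor, auto_approve = TRUE,
                       field_map = default_field_map()) {
  if (!file.exists(path)) stop("cannot read SDF: ", path, call. = FALSE)
  require_role(reg, actor, if (auto_approve) "registrar" else "submitter")
  records <- read_sdf(path)
  disp <- data.frame(record = integer(0), outcome = character(0),
                     rules = character(0), molecule_code = character(0),
                     substance_code = character(0), batch_code = integer(0),
                     message = character(0), stringsAsFactors = FALSE)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    meta <- map_record_metadata(rec$data, field_map, reg$metadata_schema)
    no_struct <- isTRUE(toupper(as.character(meta$no_structure %||% "")) %in%
                          c("TRUE", "1", "YES"))
    comp <- substance_composition()
    ratio <- NULL
    msg <- ""
    out <- tryCatch({
      if (!is.null(meta$salt) && nzchar(meta$salt)) {
        ids <- trimws(strsplit(meta$salt, ";", fixed = TRUE)[[1]])
        co <- if (!is.null(meta$salt_coeff) && nzchar(meta$salt_coeff))
          as.numeric(trimws(strsplit(meta$salt_coeff, ";", fixed = TRUE)[[1]]))
        else rep(1, length(ids))
        comp <- substance_composition(data.frame(id = ids, coeff = co))
      }
      if (!is.null(meta$hydrate) && nzchar(meta$hydrate))
        comp <- substance_composition(comp$salts, as.integer(meta$hydrate))
      if (!is.null(meta$mixture_ratio) && nzchar(meta$mixture_ratio))
        ratio <- as.integer(strsplit(meta$mixture_ratio, ":", fixed = TRUE)[[1]])
      meta_batch <- meta[setdiff(names(meta),
                                 c("salt", "salt_coeff", "hydrate",
                                   "mixture_ratio", "no_structure"))]
      if (!no_struct && is.null(rec$structure))
        stop(rec$error %||% "molfile parse failure")
      rules <- character(0)
      if (no_struct) {
        id <- submit(reg, actor, no_structure = TRUE,
                     composition = comp, metadata = meta_batch)
      } else {
        id <- submit(reg, actor, rec$structure, composition = comp,
                     metadata = meta_batch, mixture_ratio = ratio)
        rules <- strsplit(reg$submissions$rules[
          match(id, reg$submissions$id)], ",", fixed = TRUE)[[1]]
      }
      if (auto_approve) {
        res <- decide_submission(reg, actor, id, "approve",
                                 reason = "bulk import")
        list(outcome = if (length(rules)) "registered_with_warnings"
                       else "registered",
             rules = paste(rules, collapse = ","),
             molecule_code = res$molecule_code,
             substance_code = res$substance_code,
             batch_code = res$batch_code, message = "")
      } else {
        list(outcome = "submitted", rules = paste(rules, collapse = ","),
             molecule_code = NA_character_, substance_code = NA_character_,
             batch_code = id, message = "")
      }
    }, error = function(e) {
      list(outcome = "rejected", rules = "", molecule_code = NA_character_,
           substance_code = NA_character_, batch_code = NA_integer_,
           message = conditionMessage(e))
    })
    disp <- rbind(disp, data.frame(record = k, outcome = out$outcome,
                                   rules = out$rules,
                                   molecule_code = out$molecule_code,
                                   substance_code = out$substance_code,
                                   batch_code = out$batch_code,
                                   message = out$message,
                                   stringsAsFactors = FALSE))
  }
  structure(list(
    total = length(records),
    registered = sum(disp$outcome == "registered"),
    registered_with_warnings = sum(disp$outcome == "registered_with_warnings"),
    rejected = sum(disp$outcome == "rejected"),
    submitted = sum(disp$outcome == "submitted"),
    dispositions = disp), class = "ucd_import_report")
}

#' @export
print.ucd_import_report <- function(x, ...) {
  cat(sprintf(
    "<import: %d record(s) -> %d registered, %d with warnings, %d rejected%s>\n",
    x$total, x$registered, x$registered_with_warnings, x$rejected,
    if (x$submitted) sprintf(", %d awaiting review", x$submitted) else ""))
  invisible(x)
}

#' Export registered entities to SDF
#'
#' One SDF record per batch (a batch holds exactly one substance), with
#' the molecule structure (V3000 whenever stereo groups are present),
#' codes, composition and batch metadata as data fields. The output
#' re-imports to an equivalent registry.
#'
#' @param reg A [ucd_registry()].
#' @param path Output path; NULL returns the SDF text.
#' @param molecule_codes Restrict to these molecules (default: all).
#' @param include_archived Include archived batches.
#' @return Invisibly, the number of records written.
#' @export
export_sdf <- function(reg, path = NULL, molecule_codes = NULL,
                       include_archived = FALSE) {
  b <- reg$batches
  if (!include_archived) b <- b[b$status == "registered", , drop = FALSE]
  if (!is.null(molecule_codes)) {
    subs <- reg$substances$code[reg$substances$molecule_code %in%
                                  molecule_codes]
    b <- b[b$substance_code %in% subs, , drop = FALSE]
  }
  if (!nrow(b)) {
    warning("empty selection; no records exported")
    if (!is.null(path)) writeLines(character(0), path)
    return(invisible(0L))
  }
  recs <- lapply(seq_len(nrow(b)), function(k) {
    sub <- reg$substances[match(b$substance_code[k], reg$substances$code), ]
    mol <- reg$molecules[match(sub$molecule_code, reg$molecules$code), ]
    s <- if (mol$no_structure) structure_record(no_structure = TRUE)
         else read_molfile(mol$molfile)
    meta <- unjson(b$metadata[k])
    data <- character(0)
    data["MOLECULE_CODE"] <- mol$code
    data["SUBSTANCE_CODE"] <- sub$code
    data["BATCH_CODE"] <- as.character(b$code[k])
    if (mol$no_structure) data["NO_STRUCTURE"] <- "TRUE"
    if (nzchar(mol$ratio)) data["MIXTURE_RATIO"] <- mol$ratio
    sl <- unjson(sub$salts)
    if (NROW(sl)) {
      data["SALT"] <- paste(sl$id, collapse = ";")
      data["SALT_COEFF"] <- paste(format(sl$coeff, trim = TRUE),
                                  collapse = ";")
    }
    if (sub$hydrate > 0L) data["HYDRATE"] <- as.character(sub$hydrate)
    inv_map <- default_field_map()
    for (f in names(meta)) {
      tag <- names(inv_map)[match(f, inv_map)]
      data[if (is.na(tag)) f else tag] <- as.character(meta[[f]])
    }
    list(structure = s, data = data, title = mol$code)
  })
  res <- write_sdf(recs, path)
  if (is.null(path)) res else invisible(length(recs))
}
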