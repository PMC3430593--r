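# The two-stage registration workflow. A registry is a mutable
# environment: submissions accumulate in the submission area, a registrar
# approves them into the registration area (molecule / substance / batch
# tables), and every status transition appends one audit event. Nothing is
# ever deleted; emptied parents are archived by cascade.

.roles <- c(viewer = 1L, submitter = 2L, registrar = 3L)

#' Default batch metadata schema
#'
#' Field name, value type and mandatory flag for batch metadata. The schema
#' is configurable per registry; this default covers the usual bench
#' fields. `experimental_mw` accepts only numbers.
#'
#' @return data.frame with columns `field`, `type`, `mandatory`.
#' @export
default_metadata_schema <- function() {
  data.frame(
    field = c("project", "scientist", "notebook_ref", "source",
              "common_name", "experimental_mw"),
    type = c("text", "text", "text", "text", "text", "number"),
    mandatory = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Create a compound registry
#'
#' @param salt_dict Salt dictionary table ([load_salt_dictionary()]).
#' @param code_width Digits in the molecule code (default 8:
#'   `UCD00000001`).
#' @param metadata_schema Batch metadata schema
#'   ([default_metadata_schema()]).
#' @param accept_predicate Optional function(structure) -> logical deciding
#'   whether a compound belongs in the registry (the workflow's criteria
#'   table); the default accepts everything parseable.
#' @return A `ucd_registry` environment.
#' @examples
#' \donttest{
#' reg <- ucd_registry()
#' add_user(reg, "alice", "submitter", team = "flavor")
#' }
#' @export
ucd_registry <- function(salt_dict = load_salt_dictionary(),
                         code_width = 8L,
                         metadata_schema = default_metadata_schema(),
                         accept_predicate = NULL) {
  reg <- new.env(parent = emptyenv())
  reg$molecules <- data.frame(
    code = character(0), ucd_key = character(0), structure_key = character(0),
    smiles = character(0), inchi = character(0), ratio = character(0),
    no_structure = logical(0), permanent_cation = logical(0),
    molfile = character(0), status = character(0), stringsAsFactors = FALSE)
  reg$substances <- data.frame(
    code = character(0), molecule_code = character(0), letter = character(0),
    comp_key = character(0), salts = character(0), hydrate = integer(0),
    mass = numeric(0), status = character(0), stringsAsFactors = FALSE)
  reg$batches <- data.frame(
    code = integer(0), substance_code = character(0), metadata = character(0),
    restricted = character(0), status = character(0), stringsAsFactors = FALSE)
  reg$submissions <- data.frame(
    id = integer(0), submitter = character(0), state = character(0),
    raw = character(0), molfile = character(0), rules = character(0),
    proton_delta = integer(0), permanent_cation = logical(0),
    no_structure = logical(0), ucd_key = character(0),
    structure_key = character(0), smiles = character(0), inchi = character(0),
    ratio = character(0), salts = character(0), hydrate = integer(0),
    metadata = character(0), restricted = character(0),
    reason = character(0), stringsAsFactors = FALSE)
  reg$audit <- data.frame(
    seq = integer(0), timestamp = character(0), actor = character(0),
    action = character(0), entity = character(0), prior = character(0),
    new = character(0), reason = character(0), stringsAsFactors = FALSE)
  reg$users <- data.frame(id = character(0), role = character(0),
                          team = character(0), stringsAsFactors = FALSE)
  reg$next_molecule <- 1L
  reg$next_batch <- 1L
  reg$salt_dict <- salt_dict
  reg$code_width <- as.integer(code_width)
  reg$metadata_schema <- metadata_schema
  reg$accept_predicate <- accept_predicate
  class(reg) <- "ucd_registry"
  reg
}

#' @export
print.ucd_registry <- function(x, ...) {
  cat(sprintf(
    "<ucd_registry: %d molecule(s), %d substance(s), %d batch(es), %d submission(s), %d audit event(s)>\n",
    nrow(x$molecules), nrow(x$substances), nrow(x$batches),
    nrow(x$submissions), nrow(x$audit)))
  invisible(x)
}

#' Add a user to a registry
#'
#' @param reg A [ucd_registry()].
#' @param id User id.
#' @param role `"viewer"`, `"submitter"`, or `"registrar"`.
#' @param team Team tag used for restricted-field visibility.
#' @return The user id, invisibly.
#' @export
add_user <- function(reg, id, role = c("viewer", "submitter", "registrar"),
                     team = "") {
  role <- match.arg(role)
  if (id %in% reg$users$id) stop("user already exists: ", id, call. = FALSE)
  reg$users <- rbind(reg$users,
                     data.frame(id = id, role = role, team = team,
                                stringsAsFactors = FALSE))
  invisible(id)
}

lookup_user <- function(reg, id) {
  k <- match(id, reg$users$id)
  if (is.na(k)) stop("unknown user: ", id, call. = FALSE)
  reg$users[k, ]
}

require_role <- function(reg, id, minimum) {
  u <- lookup_user(reg, id)
  if (.roles[[u$role]] < .roles[[minimum]])
    stop(sprintf("user '%s' (role %s) lacks the '%s' privilege",
                 id, u$role, minimum), call. = FALSE)
  u
}

audit_event <- function(reg, actor, action, entity, prior, new, reason = "") {
  reg$audit <- rbind(reg$audit, data.frame(
    seq = nrow(reg$audit) + 1L,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
    actor = actor, action = action, entity = entity,
    prior = prior, new = new, reason = reason, stringsAsFactors = FALSE))
  invisible(NULL)
}

json <- function(x) as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
unjson <- function(x) jsonlite::fromJSON(x, simplifyVector = TRUE)

ratio_string <- function(mixture_ratio) {
  r <- normalize_ratio(mixture_ratio)
  if (is.null(r)) "" else paste(r, collapse = ":")
}

check_metadata <- function(schema, metadata) {
  for (k in seq_len(nrow(schema))) {
    f <- schema$field[k]
    v <- metadata[[f]]
    if (schema$mandatory[k] && (is.null(v) || !nzchar(trimws(as.character(v)))))
      stop("mandatory metadata field missing: ", f, call. = FALSE)
    if (!is.null(v) && schema$type[k] == "number") {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num))
        stop("metadata field '", f, "' accepts only numbers (got '", v, "')",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Submit a structure for registration
#'
#' Runs the full entry pipeline: parse, [standardize()] (the submitter must
#' approve the normalized form), [validate_structure()] (any error refuses
#' the submission), mandatory-metadata checks, then files the submission in
#' the submission area under a fresh incremental submission id. The
#' registration area is untouched until a registrar decides.
#'
#' @param reg A [ucd_registry()].
#' @param user Submitting user id (role submitter or registrar).
#' @param structure Structure text (SMILES or molfile), or a
#'   [structure_record()]; ignored when `no_structure` is TRUE.
#' @param composition A [substance_composition()].
#' @param metadata Named list of batch metadata.
#' @param restricted Named list of team-restricted fields:
#'   `list(field = list(team = , value = ))`.
#' @param mixture_ratio Optional stereoisomer mixture ratio.
#' @param no_structure TRUE files a No Structure entry.
#' @param approve_normalization The submitter's sign-off on the normalized
#'   structure; submission is refused without it.
#' @return The submission id (also the future batch code), invisibly.
#' @export
submit <- function(reg, user, structure = NULL,
                   composition = substance_composition(),
                   metadata = list(), restricted = list(),
                   mixture_ratio = NULL, no_structure = FALSE,
                   approve_normalization = TRUE) {
  require_role(reg, user, "submitter")
  if (!isTRUE(approve_normalization))
    stop("submission requires the submitter's approval of the normalized structure",
         call. = FALSE)
  check_metadata(reg$metadata_schema, metadata)
  if (no_structure) {
    s <- structure_record(no_structure = TRUE)
    norm <- list(structure = s, applied_rules = character(0),
                 proton_delta = 0L, permanent_cation = FALSE)
    keys <- list(ucd_key = NA_character_, structure_key = NA_character_,
                 canonical_smiles = NA_character_, inchi = NA_character_)
    raw <- ""
  } else {
    if (is.null(structure)) stop("no structure given", call. = FALSE)
    s0 <- if (inherits(structure, "ucd_structure")) structure
          else parse_structure(structure)
    raw <- if (is.character(structure)) paste(structure, collapse = "\n")
           else write_molfile(s0)
    if (!is.null(reg$accept_predicate) && !isTRUE(reg$accept_predicate(s0)))
      stop("structure does not meet the registry's inclusion criteria",
           call. = FALSE)
    norm <- standardize(s0)
    rep <- validate_structure(norm$structure)
    if (!rep$registrable)
      stop("validation errors: ",
           paste(sprintf("[%s@%d] %s", rep$errors$rule, rep$errors$locus,
                         rep$errors$message), collapse = "; "),
           call. = FALSE)
    keys <- canonical_keys(norm$structure, mixture_ratio)
  }
  # composition must resolve now, not at approval time
  if (nrow(composition$salts) &&
      !all(composition$salts$id %in% reg$salt_dict$id))
    stop("unknown salt id in composition", call. = FALSE)
  id <- reg$next_batch
  reg$next_batch <- reg$next_batch + 1L
  reg$submissions <- rbind(reg$submissions, data.frame(
    id = id, submitter = user, state = "submitted",
    raw = raw,
    molfile = if (no_structure) "" else write_molfile(norm$structure),
    rules = paste(norm$applied_rules, collapse = ","),
    proton_delta = norm$proton_delta,
    permanent_cation = norm$permanent_cation,
    no_structure = no_structure,
    ucd_key = keys$ucd_key, structure_key = keys$structure_key,
    smiles = keys$canonical_smiles, inchi = keys$inchi,
    ratio = ratio_string(mixture_ratio),
    salts = json(composition$salts), hydrate = composition$hydrate,
    metadata = json(metadata), restricted = json(restricted),
    reason = "", stringsAsFactors = FALSE))
  audit_event(reg, user, "submission_created", paste0("submission:", id),
              "", "submitted")
  invisible(id)
}

molecule_code <- function(reg, n) sprintf("UCD%0*d", reg$code_width, n)

# bijective base-26 letters: 1->A ... 26->Z, 27->AA, ...
substance_letter <- function(n) {
  out <- ""
  while (n > 0L) {
    r <- (n - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    n <- (n - 1L) %/% 26L
  }
  out
}

# uniqueness resolution: find-or-mint the molecule for a submission row.
# No Structure entries never merge; archived matches are reactivated.
resolve_molecule <- function(reg, actor, row) {
  if (row$no_structure) {
    code <- molecule_code(reg, reg$next_molecule)
    reg$next_molecule <- reg$next_molecule + 1L
    reg$molecules <- rbind(reg$molecules, data.frame(
      code = code, ucd_key = paste0("NOSTRUCT:", code),
      structure_key = paste0("NOSTRUCT:", code),
      smiles = NA_character_, inchi = NA_character_, ratio = "",
      no_structure = TRUE, permanent_cation = FALSE, molfile = "",
      status = "active", stringsAsFactors = FALSE))
    audit_event(reg, actor, "molecule_registered", paste0("molecule:", code),
                "", "active")
    return(code)
  }
  hit <- which(reg$molecules$ucd_key == row$ucd_key)
  if (length(hit)) {
    code <- reg$molecules$code[hit[1]]
    if (reg$molecules$status[hit[1]] == "archived") {
      reg$molecules$status[hit[1]] <- "active"
      audit_event(reg, actor, "molecule_reactivated",
                  paste0("molecule:", code), "archived", "active")
    }
    return(code)
  }
  code <- molecule_code(reg, reg$next_molecule)
  reg$next_molecule <- reg$next_molecule + 1L
  reg$molecules <- rbind(reg$molecules, data.frame(
    code = code, ucd_key = row$ucd_key, structure_key = row$structure_key,
    smiles = row$smiles, inchi = row$inchi, ratio = row$ratio,
    no_structure = FALSE, permanent_cation = row$permanent_cation,
    molfile = row$molfile, status = "active", stringsAsFactors = FALSE))
  audit_event(reg, actor, "molecule_registered", paste0("molecule:", code),
              "", "active")
  code
}

resolve_substance <- function(reg, actor, mol_code, comp, no_structure,
                              molfile) {
  ck <- composition_key(comp)
  hit <- which(reg$substances$molecule_code == mol_code &
               reg$substances$comp_key == ck)
  if (length(hit)) {
    code <- reg$substances$code[hit[1]]
    if (reg$substances$status[hit[1]] == "archived") {
      reg$substances$status[hit[1]] <- "active"
      audit_event(reg, actor, "substance_reactivated",
                  paste0("substance:", code), "archived", "active")
    }
    return(code)
  }
  n <- sum(reg$substances$molecule_code == mol_code) + 1L
  code <- paste0(mol_code, "-", substance_letter(n))
  mass <- if (no_structure) NA_real_ else
    substance_mass(read_molfile(molfile), comp, reg$salt_dict)$total
  reg$substances <- rbind(reg$substances, data.frame(
    code = code, molecule_code = mol_code, letter = substance_letter(n),
    comp_key = ck, salts = json(comp$salts), hydrate = comp$hydrate,
    mass = mass, status = "active", stringsAsFactors = FALSE))
  audit_event(reg, actor, "substance_registered", paste0("substance:", code),
              "", "active")
  code
}

row_composition <- function(row) {
  sl <- unjson(row$salts)
  if (!length(sl) || !NROW(sl)) sl <- NULL
  substance_composition(sl, row$hydrate)
}

#' Decide on a submission
#'
#' Registrar review of a submitted entry. Approval resolves uniqueness
#' (an existing molecule with the same key is reused, an archived one
#' reactivated, otherwise the next code is minted; likewise for the
#' substance letter) and creates the registered batch whose code equals
#' the submission id. Rejection records the reason; the submitter may
#' modify and resubmit under a fresh id.
#'
#' @param reg A [ucd_registry()].
#' @param user Deciding user id (must be a registrar).
#' @param submission_id Id returned by [submit()].
#' @param decision `"approve"` or `"reject"`.
#' @param reason Free-text reason (mandatory for rejections in spirit).
#' @return For approvals, list(molecule_code, substance_code, batch_code);
#'   for rejections, NULL invisibly.
#' @export
decide_submission <- function(reg, user, submission_id,
                              decision = c("approve", "reject"),
                              reason = "") {
  decision <- match.arg(decision)
  require_role(reg, user, "registrar")
  k <- match(submission_id, reg$submissions$id)
  if (is.na(k)) stop("no such submission: ", submission_id, call. = FALSE)
  row <- reg$submissions[k, ]
  if (row$state != "submitted")
    stop("submission ", submission_id, " is not awaiting decision (state ",
         row$state, ")", call. = FALSE)
  if (decision == "reject") {
    reg$submissions$state[k] <- "rejected"
    reg$submissions$reason[k] <- reason
    audit_event(reg, user, "submission_rejected",
                paste0("submission:", submission_id), "submitted",
                "rejected", reason)
    return(invisible(NULL))
  }
  mol_code <- resolve_molecule(reg, user, row)
  sub_code <- resolve_substance(reg, user, mol_code, row_composition(row),
                                row$no_structure, row$molfile)
  reg$batches <- rbind(reg$batches, data.frame(
    code = row$id, substance_code = sub_code, metadata = row$metadata,
    restricted = row$restricted, status = "registered",
    stringsAsFactors = FALSE))
  reg$submissions$state[k] <- "approved"
  audit_event(reg, user, "submission_approved",
              paste0("submission:", submission_id), "submitted", "approved",
              reason)
  audit_event(reg, user, "batch_registered", paste0("batch:", row$id),
              "", "registered")
  list(molecule_code = mol_code, substance_code = sub_code,
       batch_code = row$id)
}

# archive-if-empty cascade after a batch leaves a substance
cascade_archive <- function(reg, actor, substance_code, reason) {
  sk <- match(substance_code, reg$substances$code)
  if (is.na(sk) || reg$substances$status[sk] == "archived") return(invisible())
  live <- sum(reg$batches$substance_code == substance_code &
              reg$batches$status == "registered")
  if (live > 0L) return(invisible())
  reg$substances$status[sk] <- "archived"
  audit_event(reg, actor, "substance_archived",
              paste0("substance:", substance_code), "active", "archived",
              reason)
  mol <- reg$substances$molecule_code[sk]
  mk <- match(mol, reg$molecules$code)
  live_sub <- sum(reg$substances$molecule_code == mol &
                  reg$substances$status == "active")
  if (live_sub == 0L && reg$molecules$status[mk] == "active") {
    reg$molecules$status[mk] <- "archived"
    audit_event(reg, actor, "molecule_archived", paste0("molecule:", mol),
                "active", "archived", reason)
  }
  invisible()
}

#' Reassign a batch to a different substance
#'
#' Used after a drawing error is discovered or a No Structure entry is
#' finally elucidated. The target resolves through the same uniqueness path
#' as an approval (molecule and substance are reused or minted). If the
#' source substance is left with no registered batches it is archived, and
#' the source molecule likewise when its last active substance goes;
#' nothing is deleted and every change is audited.
#'
#' @param reg A [ucd_registry()].
#' @param user Acting registrar.
#' @param batch_code Code of a registered batch.
#' @param structure Target structure text or [structure_record()], or NULL
#'   with `no_structure = TRUE`.
#' @param composition Target [substance_composition()].
#' @param mixture_ratio Target mixture ratio.
#' @param no_structure TRUE re-homes the batch to a No Structure molecule.
#' @param reason Audit reason.
#' @return list(molecule_code, substance_code, batch_code) of the new home.
#' @export
reassign_batch <- function(reg, user, batch_code, structure = NULL,
                           composition = substance_composition(),
                           mixture_ratio = NULL, no_structure = FALSE,
                           reason = "") {
  require_role(reg, user, "registrar")
  bk <- match(batch_code, reg$batches$code)
  if (is.na(bk)) stop("no such batch: ", batch_code, call. = FALSE)
  if (reg$batches$status[bk] != "registered")
    stop("batch ", batch_code, " is not in a reassignable state (",
         reg$batches$status[bk], ")", call. = FALSE)
  if (no_structure) {
    row <- list(no_structure = TRUE)
  } else {
    s0 <- if (inherits(structure, "ucd_structure")) structure
          else parse_structure(structure)
    norm <- standardize(s0)
    rep <- validate_structure(norm$structure)
    if (!rep$registrable)
      stop("target structure fails validation", call. = FALSE)
    keys <- canonical_keys(norm$structure, mixture_ratio)
    row <- list(no_structure = FALSE, ucd_key = keys$ucd_key,
                structure_key = keys$structure_key,
                smiles = keys$canonical_smiles, inchi = keys$inchi,
                ratio = ratio_string(mixture_ratio),
                permanent_cation = norm$permanent_cation,
                molfile = write_molfile(norm$structure))
  }
  old_sub <- reg$batches$substance_code[bk]
  mol_code <- resolve_molecule(reg, user, row)
  sub_code <- resolve_substance(reg, user, mol_code, composition,
                                no_structure,
                                if (no_structure) "" else row$molfile)
  reg$batches$substance_code[bk] <- sub_code
  audit_event(reg, user, "batch_reassigned", paste0("batch:", batch_code),
              old_sub, sub_code, reason)
  cascade_archive(reg, user, old_sub, paste0("emptied by reassignment of batch ",
                                             batch_code))
  list(molecule_code = mol_code, substance_code = sub_code,
       batch_code = batch_code)
}

#' Archive a batch
#'
#' The batch record is retained with status archived; emptied parents are
#' archived by cascade. There is no delete.
#'
#' @param reg A [ucd_registry()].
#' @param user Acting registrar.
#' @param batch_code Code of a registered batch.
#' @param reason Audit reason.
#' @return Invisibly, the batch code.
#' @export
archive_batch <- function(reg, user, batch_code, reason = "") {
  require_role(reg, user, "registrar")
  bk <- match(batch_code, reg$batches$code)
  if (is.na(bk)) stop("no such batch: ", batch_code, call. = FALSE)
  if (reg$batches$status[bk] != "registered")
    stop("batch ", batch_code, " is already ", reg$batches$status[bk],
         call. = FALSE)
  reg$batches$status[bk] <- "archived"
  audit_event(reg, user, "batch_archived", paste0("batch:", batch_code),
              "registered", "archived", reason)
  cascade_archive(reg, user, reg$batches$substance_code[bk],
                  paste0("emptied by archiving of batch ", batch_code))
  invisible(batch_code)
}

#' Read a batch metadata field under access control
#'
#' Public fields are visible to any authenticated user; a restricted field
#' is returned only when the reader's team matches the field's team,
#' otherwise the masked marker is returned.
#'
#' @param reg A [ucd_registry()].
#' @param user Reading user id (must exist).
#' @param batch_code Batch code.
#' @param field Field name.
#' @return The value, or the string `"<masked>"` for a restricted field of
#'   another team, or NULL when the field is absent.
#' @export
enforce_access <- function(reg, user, batch_code, field) {
  u <- lookup_user(reg, user)
  bk <- match(batch_code, reg$batches$code)
  if (is.na(bk)) stop("no such batch: ", batch_code, call. = FALSE)
  meta <- unjson(reg$batches$metadata[bk])
  if (field %in% names(meta)) return(meta[[field]])
  restr <- unjson(reg$batches$restricted[bk])
  if (field %in% names(restr)) {
    entry <- restr[[field]]
    if (identical(entry$team, u$team)) return(entry$value)
    return("<masked>")
  }
  NULL
}

#' Registry audit log
#' @param reg A [ucd_registry()].
#' @return data.frame of audit events in order.
#' @export
audit_log <- function(reg) reg$audit

#' Registration-area tables
#'
#' Accessors for the molecule, substance, and batch tables of the
#' registration area and the submission-area table.
#'
#' @param reg A [ucd_registry()].
#' @param include_archived Include archived rows (default TRUE; these are
#'   full-table accessors, search applies its own flag).
#' @return data.frame.
#' @export
molecules <- function(reg, include_archived = TRUE) {
  m <- reg$molecules
  if (!include_archived) m <- m[m$status == "active", , drop = FALSE]
  m
}

#' @rdname molecules
#' @export
substances <- function(reg, include_archived = TRUE) {
  s <- reg$substances
  if (!include_archived) s <- s[s$status == "active", , drop = FALSE]
  s
}

#' @rdname molecules
#' @export
batches <- function(reg, include_archived = TRUE) {
  b <- reg$batches
  if (!include_archived) b <- b[b$status == "registered", , drop = FALSE]
  b
}

#' @rdname molecules
#' @export
submissions <- function(reg, include_archived = TRUE) reg$submissions

#' Save or load a registry as JSON
#'
#' Plain-text persistence of all registry tables and counters. The salt
#' dictionary, metadata schema and code width travel with the file; an
#' `accept_predicate` does not (functions are not serialized) and must be
#' re-attached after loading if one was configured.
#'
#' @param reg A [ucd_registry()].
#' @param path JSON file path.
#' @return `save_registry` the path invisibly; `load_registry` a
#'   `ucd_registry`.
#' @export
save_registry <- function(reg, path) {
  payload <- list(
    molecules = reg$molecules, substances = reg$substances,
    batches = reg$batches, submissions = reg$submissions,
    audit = reg$audit, users = reg$users,
    next_molecule = reg$next_molecule, next_batch = reg$next_batch,
    salt_dict = reg$salt_dict, code_width = reg$code_width,
    metadata_schema = reg$metadata_schema)
  jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname save_registry
#' @export
load_registry <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fix <- function(df, proto) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (!nrow(df) && !length(df)) return(proto)
    for (col in names(proto)) {
      if (!col %in% names(df)) df[[col]] <- proto[[col]][0]
      mode_fun <- switch(class(proto[[col]]),
                         integer = as.integer, numeric = as.numeric,
                         logical = as.logical, as.character)
      df[[col]] <- mode_fun(df[[col]])
      if (is.character(proto[[col]]) && col %in% c("reason", "ratio"))
        df[[col]][is.na(df[[col]])] <- ""
    }
    df[names(proto)]
  }
  reg <- ucd_registry(salt_dict = as.data.frame(p$salt_dict,
                                                stringsAsFactors = FALSE),
                      code_width = as.integer(p$code_width),
                      metadata_schema = as.data.frame(p$metadata_schema,
                                                      stringsAsFactors = FALSE))
  reg$molecules <- fix(p$molecules, reg$molecules)
  reg$substances <- fix(p$substances, reg$substances)
  reg$batches <- fix(p$batches, reg$batches)
  reg$submissions <- fix(p$submissions, reg$submissions)
  reg$audit <- fix(p$audit, reg$audit)
  reg$users <- fix(p$users, reg$users)
  reg$next_molecule <- as.integer(p$next_molecule)
  reg$next_batch <- as.integer(p$next_batch)
  reg
}

#' Replay the audit log into entity statuses
#'
#' Reconstructs the final status of every audited entity from the event
#' stream alone; used to verify that the audit trail is complete.
#'
#' @param reg A [ucd_registry()].
#' @return Named character vector entity -> status.
#' @export
replay_audit <- function(reg) {
  st <- character(0)
  for (k in seq_len(nrow(reg$audit))) {
    ev <- reg$audit[k, ]
    if (ev$action == "batch_reassigned") next  # substance link, not status
    st[ev$entity] <- ev$new
  }
  st
}
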