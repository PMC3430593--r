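#' Chemical structure record
#'
#' The unit of chemical identity: an annotated molecular graph with formal
#' charges, wedge bonds, enhanced stereo groups (absolute / AND / OR) and an
#' optional "No Structure" flag for registrable entries whose structure is
#' unknown (e.g. an unidentified MS peak).
#'
#' @param atoms data.frame with columns `elem` (symbol), `charge` (integer),
#'   `isotope` (integer or NA), `hcount` (explicit hydrogen count, NA means
#'   derive from standard valence), `x`, `y` (2D depiction coordinates).
#' @param bonds data.frame with columns `i`, `j` (0-based atom indices),
#'   `order` (1, 2, 3, or 4 for aromatic), `wedge` (one of `"none"`, `"up"`,
#'   `"down"`, `"either"`; narrow end at atom `i`).
#' @param stereo_groups list of [stereo_group()] annotations.
#' @param no_structure logical; `TRUE` marks a No Structure placeholder with
#'   an empty graph.
#' @return An object of class `ucd_structure`.
#' @examples
#' # methane
#' structure_record(data.frame(elem = "C", charge = 0L, isotope = NA_integer_,
#'                             hcount = NA_integer_, x = 0, y = 0))
#' @export
structure_record <- function(atoms = empty_atoms(), bonds = empty_bonds(),
                             stereo_groups = list(), no_structure = FALSE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  for (col in c("elem", "charge", "isotope", "hcount", "x", "y"))
    if (!col %in% names(atoms)) {
      atoms[[col]] <- if (col == "elem") character(0) else
        switch(col, charge = 0L, isotope = NA_integer_,
               hcount = NA_integer_, x = 0, y = 0)
    }
  if (!nrow(bonds)) bonds <- empty_bonds()
  if (!"wedge" %in% names(bonds)) bonds$wedge <- rep("none", nrow(bonds))
  s <- structure(list(atoms = atoms, bonds = bonds,
                      stereo_groups = stereo_groups,
                      no_structure = isTRUE(no_structure)),
                 class = "ucd_structure")
  check_structure(s)
  s
}

empty_atoms <- function() {
  data.frame(elem = character(0), charge = integer(0), isotope = integer(0),
             hcount = integer(0), x = numeric(0), y = numeric(0),
             stringsAsFactors = FALSE)
}

empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = integer(0),
             wedge = character(0), stringsAsFactors = FALSE)
}

#' Enhanced stereo group annotation
#'
#' V3000-style stereo collection: `absolute` asserts the drawn configuration
#' of its member centers as absolute; `and` declares a mixture of the drawn
#' configuration and its mirror image at the member centers; `or` declares a
#' single (enantiopure) but unknown one of the two.
#'
#' @param kind `"absolute"`, `"and"`, or `"or"`.
#' @param atoms integer vector of 0-based member stereocenter indices.
#' @param ordinal group number within its kind (AND1, OR2, ...).
#' @return A `ucd_stereo_group` list.
#' @export
stereo_group <- function(kind, atoms, ordinal = 1L) {
  kind <- match.arg(kind, c("absolute", "and", "or"))
  structure(list(kind = kind, atoms = as.integer(atoms),
                 ordinal = as.integer(ordinal)),
            class = "ucd_stereo_group")
}

check_structure <- function(s) {
  a <- s$atoms; b <- s$bonds
  if (s$no_structure && (nrow(a) || nrow(b)))
    stop("a No Structure record must have an empty graph", call. = FALSE)
  if (nrow(b)) {
    if (any(b$i == b$j)) stop("self-bond (i == j)", call. = FALSE)
    if (any(b$i < 0 | b$j < 0 | b$i >= nrow(a) | b$j >= nrow(a)))
      stop("bond references an atom index out of range", call. = FALSE)
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
    if (any(b$wedge != "none" & b$order != 1L))
      stop("wedge annotation on a bond of order > 1", call. = FALSE)
    if (!all(b$order %in% c(1L, 2L, 3L, 4L)))
      stop("bond order must be 1, 2, 3, or 4 (aromatic)", call. = FALSE)
  }
  for (g in s$stereo_groups) {
    if (any(g$atoms < 0L | g$atoms >= nrow(a)))
      stop("stereo group references an atom index out of range", call. = FALSE)
  }
  rel <- Filter(function(g) g$kind != "absolute", s$stereo_groups)
  ords <- vapply(rel, function(g) paste(g$kind, g$ordinal), "")
  if (anyDuplicated(ords))
    stop("duplicate stereo group ordinal within a kind", call. = FALSE)
  invisible(s)
}

#' @export
print.ucd_structure <- function(x, ...) {
  if (x$no_structure) {
    cat("<ucd_structure: No Structure>\n")
    return(invisible(x))
  }
  cat(sprintf("<ucd_structure: %s, %d heavy atoms, %d bonds, net charge %+d>\n",
              structure_formula(x), nrow(x$atoms), nrow(x$bonds),
              net_charge(x)))
  if (length(x$stereo_groups)) {
    lab <- vapply(x$stereo_groups, function(g)
      sprintf("%s%d(%s)", toupper(substr(g$kind, 1, 3)), g$ordinal,
              paste(g$atoms, collapse = ",")), "")
    cat("  stereo groups:", paste(lab, collapse = " "), "\n")
  }
  invisible(x)
}

# ---- valence model ----------------------------------------------------------

# Allowed total valences per neutral element (smallest consistent one is
# used to derive implicit hydrogens).
.valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), Cl = 1L, Se = c(2L, 4L, 6L), Br = 1L, I = 1L,
  As = c(3L, 5L)
)

# Charge-shifted valence list; NULL when the element has no standard organic
# valence model (metals etc.) -> zero implicit H, validated with a warning.
allowed_valences <- function(elem, charge) {
  v <- .valences[[elem]]
  if (is.null(v)) return(NULL)
  if (charge == 0L) return(v)
  shift <- switch(elem,
    N = charge, O = charge, S = charge, Se = charge, P = charge,
    C = -abs(charge),      # carbanion and carbocation both trivalent
    B = -charge,           # borate B- is tetravalent
    F = , Cl = , Br = , I = if (charge < 0) -1L else NA_integer_,
    NA_integer_)
  if (is.na(shift[1])) return(NULL)
  v <- v + shift
  v[v >= 0L]
}

# Sum of bond orders at each atom; aromatic (order 4) counts 1.5 and the
# total is rounded up.
bond_order_sums <- function(s) {
  n <- nrow(s$atoms)
  deg <- numeric(n)
  b <- s$bonds
  if (nrow(b)) {
    ord <- ifelse(b$order == 4L, 1.5, b$order)
    for (k in seq_len(nrow(b))) {
      deg[b$i[k] + 1L] <- deg[b$i[k] + 1L] + ord[k]
      deg[b$j[k] + 1L] <- deg[b$j[k] + 1L] + ord[k]
    }
  }
  ceiling(deg - 1e-9)
}

#' Implicit/explicit hydrogen count per atom
#'
#' Hydrogens implied by the standard valence model (or fixed by an explicit
#' `hcount` from a molfile), after accounting for formal charge.
#'
#' @param s A [structure_record()].
#' @return Integer vector, one entry per atom.
#' @export
hydrogen_counts <- function(s) {
  n <- nrow(s$atoms)
  if (!n) return(integer(0))
  bos <- bond_order_sums(s)
  out <- integer(n)
  for (k in seq_len(n)) {
    if (!is.na(s$atoms$hcount[k])) { out[k] <- s$atoms$hcount[k]; next }
    v <- allowed_valences(s$atoms$elem[k], s$atoms$charge[k])
    if (is.null(v)) { out[k] <- 0L; next }
    fit <- v[v >= bos[k]]
    out[k] <- if (length(fit)) min(fit) - bos[k] else 0L
  }
  out
}

#' Net formal charge of a structure
#' @param s A [structure_record()].
#' @return Integer net charge in elementary units.
#' @export
net_charge <- function(s) as.integer(sum(s$atoms$charge))

#' Molecular formula of a structure
#'
#' Hill-ordered formula including implicit hydrogens.
#'
#' @param s A [structure_record()].
#' @return Formula string, e.g. `"C3H3NO2"`.
#' @export
structure_formula <- function(s) {
  if (s$no_structure || !nrow(s$atoms)) return("")
  counts <- table(s$atoms$elem)
  counts <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(hydrogen_counts(s))
  counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h
  hill_formula(counts)
}

# ---- graph helpers ----------------------------------------------------------

# adjacency list (1-based list over 0-based neighbour indices)
adjacency <- function(s) {
  n <- nrow(s$atoms)
  adj <- vector("list", n)
  b <- s$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k] + 1L]] <- c(adj[[b$i[k] + 1L]], b$j[k])
    adj[[b$j[k] + 1L]] <- c(adj[[b$j[k] + 1L]], b$i[k])
  }
  adj
}

# heavy-atom degree
degrees <- function(s) {
  n <- nrow(s$atoms)
  d <- integer(n)
  if (nrow(s$bonds)) {
    t1 <- table(factor(s$bonds$i, levels = 0:(n - 1)))
    t2 <- table(factor(s$bonds$j, levels = 0:(n - 1)))
    d <- as.integer(t1 + t2)
  }
  d
}

# TRUE per bond when the bond lies on a cycle (endpoints stay connected
# after its removal).
ring_bonds <- function(s) {
  nb <- nrow(s$bonds)
  if (!nb) return(logical(0))
  out <- logical(nb)
  for (k in seq_len(nb)) {
    from <- s$bonds$i[k]; to <- s$bonds$j[k]
    seen <- from
    frontier <- from
    found <- FALSE
    while (length(frontier) && !found) {
      nxt <- integer(0)
      for (v in frontier) {
        rows <- which((s$bonds$i == v | s$bonds$j == v) & seq_len(nb) != k)
        for (r in rows) {
          w <- if (s$bonds$i[r] == v) s$bonds$j[r] else s$bonds$i[r]
          if (w == to) { found <- TRUE; break }
          if (!(w %in% seen)) { seen <- c(seen, w); nxt <- c(nxt, w) }
        }
        if (found) break
      }
      frontier <- nxt
    }
    out[k] <- found
  }
  out
}

# number of incident ring bonds per atom; >= 3 marks a ring-fusion or
# bridging atom
ring_degree <- function(s) {
  rb <- ring_bonds(s)
  n <- nrow(s$atoms)
  d <- integer(n)
  for (k in which(rb)) {
    d[s$bonds$i[k] + 1L] <- d[s$bonds$i[k] + 1L] + 1L
    d[s$bonds$j[k] + 1L] <- d[s$bonds$j[k] + 1L] + 1L
  }
  d
}

#' Atom symmetry classes (Morgan refinement)
#'
#' Iterative neighbourhood refinement of an initial invariant (element,
#' charge, degree, hydrogen count, bond-order sum). Atoms sharing a class are
#' topologically equivalent; used for stereocenter perception.
#'
#' @param s A [structure_record()].
#' @return Integer class id per atom (dense, arbitrary numbering).
#' @export
symmetry_classes <- function(s) {
  n <- nrow(s$atoms)
  if (!n) return(integer(0))
  hs <- hydrogen_counts(s)
  inv <- paste(s$atoms$elem, s$atoms$charge, degrees(s), hs, bond_order_sums(s))
  cls <- match(inv, unique(inv))
  adj <- adjacency(s)
  repeat {
    sig <- vapply(seq_len(n), function(k) {
      nb <- sort(cls[adj[[k]] + 1L])
      paste(cls[k], paste(nb, collapse = ","))
    }, "")
    new <- match(sig, unique(sig))
    if (length(unique(new)) == length(unique(cls))) return(new)
    cls <- new
  }
}

#' Potential tetrahedral stereocenters
#'
#' An sp3 atom whose substituents (including at most one implicit hydrogen)
#' fall in pairwise distinct symmetry classes. This Morgan-class criterion
#' covers ordinary stereocenters; para-substituted and meso symmetry is
#' excluded by construction.
#'
#' @param s A [structure_record()].
#' @return Integer vector of 0-based atom indices.
#' @export
potential_stereocenters <- function(s) {
  n <- nrow(s$atoms)
  if (!n) return(integer(0))
  cls <- symmetry_classes(s)
  hs <- hydrogen_counts(s)
  adj <- adjacency(s)
  bos <- bond_order_sums(s)
  deg <- degrees(s)
  out <- integer(0)
  for (k in seq_len(n)) {
    if (bos[k] != deg[k]) next           # any multiple bond -> not sp3 here
    nsub <- deg[k] + hs[k]
    if (nsub != 4L || hs[k] > 1L) next
    ncls <- cls[adj[[k]] + 1L]
    if (hs[k] == 1L) ncls <- c(ncls, -1L)  # implicit H: its own class
    if (!anyDuplicated(ncls)) out <- c(out, k - 1L)
  }
  out
}

# wedge bonds whose narrow end (atom i) is the given 0-based atom
wedges_at <- function(s, atom) {
  which(s$bonds$wedge %in% c("up", "down") & s$bonds$i == atom)
}

# 0-based indices of atoms touched by an "either" (wavy) bond
either_centers <- function(s) {
  w <- s$bonds$wedge == "either"
  sort(unique(c(s$bonds$i[w], s$bonds$j[w])))
}

# strict same-order structural equality; canonical keys compare chemistry
same_structure <- function(a, b) {
  isTRUE(all.equal(a$atoms[c("elem", "charge", "isotope", "hcount")],
                   b$atoms[c("elem", "charge", "isotope", "hcount")],
                   check.attributes = FALSE)) &&
    isTRUE(all.equal(a$bonds, b$bonds, check.attributes = FALSE)) &&
    identical(a$no_structure, b$no_structure)
}
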