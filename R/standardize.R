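# Structure standardization and validation. Rules mirror corporate drawing
# standards: neutralize ionizable centers (quaternary ammonium exempt),
# orient wedges to the stereocenter, drop redundant wedges, straighten
# triple-bond geometry. Unfixable problems are the validator's business.

#' @export
print.ucd_normalization <- function(x, ...) {
  cat(sprintf("<normalization: %d rule(s) applied [%s], proton delta %+d%s>\n",
              length(x$applied_rules),
              paste(x$applied_rules, collapse = ", "), x$proton_delta,
              if (x$permanent_cation) ", permanent cation" else ""))
  invisible(x)
}

# quaternary ammonium: N+ with four non-hydrogen substituents, permanently
# charged independent of pH and therefore exempt from neutralization
is_quaternary_n <- function(s) {
  deg <- degrees(s)
  hs <- hydrogen_counts(s)
  s$atoms$elem == "N" & s$atoms$charge == 1L & deg == 4L & hs == 0L
}

#' Neutralize charged centers
#'
#' Every ionizable charged atom is converted to its neutral form; under the
#' standard valence model this adds one hydrogen per unit negative charge
#' (carboxylate to acid) and removes one per unit positive charge
#' (ammonium to amine). Quaternary ammonium nitrogens are left charged and
#' flagged. The heavy-atom graph is untouched.
#'
#' @param s A [structure_record()].
#' @return A `ucd_normalization` list: `structure`, `applied_rules`,
#'   `proton_delta` (hydrogens added minus removed), `permanent_cation`.
#' @examples
#' \donttest{
#' neutralize(parse_structure("N#CCC(=O)[O-]"))$proton_delta  # +1
#' }
#' @export
neutralize <- function(s) {
  check_structure(s)
  if (s$no_structure)
    return(structure(list(structure = s, applied_rules = character(0),
                          proton_delta = 0L, permanent_cation = FALSE),
                     class = "ucd_normalization"))
  h_before <- hydrogen_counts(s)
  quat <- is_quaternary_n(s)
  out <- s
  bos <- bond_order_sums(s)
  changed <- FALSE
  for (k in seq_len(nrow(s$atoms))) {
    ch <- s$atoms$charge[k]
    if (ch == 0L || quat[k]) next
    v0 <- allowed_valences(s$atoms$elem[k], 0L)
    if (is.null(v0) || !any(v0 >= bos[k]))
      stop(sprintf(
        "atom %d (%s%+d) cannot be neutralized by hydrogen transfer and is not a recognized permanent cation",
        k - 1L, s$atoms$elem[k], ch), call. = FALSE)
    out$atoms$charge[k] <- 0L
    changed <- TRUE
  }
  delta <- sum(hydrogen_counts(out)) - sum(h_before)
  structure(list(structure = out,
                 applied_rules = if (changed) "neutralize" else character(0),
                 proton_delta = as.integer(delta),
                 permanent_cation = any(quat)),
            class = "ucd_normalization")
}

# angle (degrees) at vertex b of a-b-c in the 2D depiction
angle_deg <- function(ax, ay, bx, by, cx, cy) {
  v1 <- c(ax - bx, ay - by); v2 <- c(cx - bx, cy - by)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) return(0)
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Standardize a structure
#'
#' Applies, in order: (1) [neutralize()]; (2) re-point wedges so the narrow
#' end sits on the stereocenter; (3) drop redundant wedges so each
#' stereocenter keeps at most one up and one down wedge; (4) straighten
#' the 2D geometry through triple bonds to 180 degrees. Re-applying the
#' result is the identity (idempotence), with an empty rule list.
#'
#' @param s A [structure_record()].
#' @return A `ucd_normalization` (see [neutralize()]); `applied_rules`
#'   lists every rule that changed the record.
#' @export
standardize <- function(s) {
  res <- neutralize(s)
  out <- res$structure
  rules <- res$applied_rules
  if (out$no_structure)
    return(structure(list(structure = out, applied_rules = rules,
                          proton_delta = res$proton_delta,
                          permanent_cation = res$permanent_cation),
                     class = "ucd_normalization"))

  centers <- potential_stereocenters(out)
  # (2) wedge narrow end must sit on the stereocenter (Fig 7c class)
  fixed <- FALSE
  for (k in which(out$bonds$wedge %in% c("up", "down"))) {
    i <- out$bonds$i[k]; j <- out$bonds$j[k]
    if (!(i %in% centers) && (j %in% centers)) {
      out$bonds$i[k] <- j; out$bonds$j[k] <- i
      fixed <- TRUE
    }
  }
  if (fixed) rules <- c(rules, "wedge_to_stereocenter")

  # (3) at most one up and one down wedge per stereocenter
  dropped <- FALSE
  for (ctr in centers) {
    for (dir in c("up", "down")) {
      w <- which(out$bonds$i == ctr & out$bonds$wedge == dir)
      if (length(w) > 1L) {
        out$bonds$wedge[w[-1]] <- "none"
        dropped <- TRUE
      }
    }
  }
  if (dropped) rules <- c(rules, "redundant_wedges")

  # (4) substituents on triple-bond atoms forced collinear (nitriles drawn
  # linearly; non-perspective geometry)
  moved <- FALSE
  adj <- adjacency(out)
  for (k in which(out$bonds$order == 3L)) {
    ends <- c(out$bonds$i[k], out$bonds$j[k])
    for (e in 1:2) {
      a <- ends[e]; b <- ends[3 - e]
      for (c0 in setdiff(adj[[a + 1L]], b)) {
        ang <- angle_deg(out$atoms$x[b + 1], out$atoms$y[b + 1],
                         out$atoms$x[a + 1], out$atoms$y[a + 1],
                         out$atoms$x[c0 + 1], out$atoms$y[c0 + 1])
        if (abs(ang - 180) > 2) {
          d <- c(out$atoms$x[a + 1] - out$atoms$x[b + 1],
                 out$atoms$y[a + 1] - out$atoms$y[b + 1])
          d <- d / sqrt(sum(d^2))
          L <- sqrt((out$atoms$x[c0 + 1] - out$atoms$x[a + 1])^2 +
                    (out$atoms$y[c0 + 1] - out$atoms$y[a + 1])^2)
          out$atoms$x[c0 + 1] <- out$atoms$x[a + 1] + d[1] * L
          out$atoms$y[c0 + 1] <- out$atoms$y[a + 1] + d[2] * L
          moved <- TRUE
        }
      }
    }
  }
  if (moved) rules <- c(rules, "linear_triple_bond")

  structure(list(structure = out, applied_rules = rules,
                 proton_delta = res$proton_delta,
                 permanent_cation = res$permanent_cation),
            class = "ucd_normalization")
}

# geometric parity of a stereocenter from wedges and 2D coordinates.
# Explicit neighbours are ordered by `ranks` (ascending; an implicit
# hydrogen ranks last); the sign of the signed volume with wedge-derived z
# is the parity. Returns +1/-1, 0 when the geometry is degenerate, NA when
# no up/down wedge informs the center.
geom_parity <- function(s, center, ranks) {
  nb_rows <- which(s$bonds$i == center | s$bonds$j == center)
  nbs <- ifelse(s$bonds$i[nb_rows] == center, s$bonds$j[nb_rows],
                s$bonds$i[nb_rows])
  z <- numeric(length(nbs))
  informed <- FALSE
  for (t in seq_along(nb_rows)) {
    r <- nb_rows[t]
    if (s$bonds$wedge[r] %in% c("up", "down") && s$bonds$i[r] == center) {
      z[t] <- if (s$bonds$wedge[r] == "up") 1 else -1
      informed <- TRUE
    }
  }
  if (!informed) return(NA_real_)
  ord <- order(ranks[nbs + 1L])
  nbs <- nbs[ord]; z <- z[ord]
  cx <- s$atoms$x[center + 1L]; cy <- s$atoms$y[center + 1L]
  v <- cbind(s$atoms$x[nbs + 1L] - cx, s$atoms$y[nbs + 1L] - cy, z)
  det3 <- function(m) {
    m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
    m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  }
  d <- if (nrow(v) == 4L) {
    det3(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))
  } else if (nrow(v) == 3L) {
    det3(v)          # implicit H sits at the center, ranked last
  } else return(0)
  if (abs(d) < 1e-6) 0 else sign(d)
}

#' Validate a structure for registrability
#'
#' Detects the unfixable drawing problems: valence violations, stereo bonds
#' on ring-fusion/bridging atoms, wedges not anchored at a stereocenter
#' (ambiguous stereochemistry), and stereocenters whose configuration the
#' drawn wedges cannot determine. Potential stereocenters left unmarked
#' yield warnings, as do elements outside the standard organic valence
#' model. An empty error table means the structure is registrable.
#'
#' @param s A [structure_record()]; run [standardize()] first for the
#'   wedge-orientation rules to have been applied.
#' @return A `ucd_validation` list with data.frames `errors` and
#'   `warnings` (columns `rule`, `locus`, `message`) and the logical
#'   `registrable`.
#' @export
validate_structure <- function(s) {
  err <- warn <- data.frame(rule = character(0), locus = integer(0),
                            message = character(0), stringsAsFactors = FALSE)
  add <- function(tab, rule, locus, msg)
    rbind(tab, data.frame(rule = rule, locus = as.integer(locus),
                          message = msg, stringsAsFactors = FALSE))
  if (s$no_structure || !nrow(s$atoms))
    return(structure(list(errors = err, warnings = warn, registrable = TRUE),
                     class = "ucd_validation"))
  bos <- bond_order_sums(s)
  for (k in seq_len(nrow(s$atoms))) {
    v <- allowed_valences(s$atoms$elem[k], s$atoms$charge[k])
    if (is.null(v)) {
      warn <- add(warn, "nonstandard_element", k - 1L,
                  sprintf("no valence model for %s charge %+d; accepted as drawn",
                          s$atoms$elem[k], s$atoms$charge[k]))
    } else if (bos[k] > max(v)) {
      err <- add(err, "valence", k - 1L,
                 sprintf("valence %d exceeds maximum %d for %s%+d",
                         bos[k], max(v), s$atoms$elem[k], s$atoms$charge[k]))
    }
  }
  centers <- potential_stereocenters(s)
  rdeg <- ring_degree(s)
  cls <- symmetry_classes(s)
  for (k in which(s$bonds$wedge %in% c("up", "down"))) {
    i <- s$bonds$i[k]; j <- s$bonds$j[k]
    if (rdeg[i + 1L] >= 3L || rdeg[j + 1L] >= 3L) {
      err <- add(err, "bridge_stereo", i,
                 "stereo bond on a bridging/ring-fusion atom; draw the explicit hydrogen instead")
    } else if (!(i %in% centers) && !(j %in% centers)) {
      # narrow end off-center but fixable by re-pointing is standardize's
      # job; a wedge touching no stereocenter at all is ambiguous
      err <- add(err, "ambiguous_stereo", i,
                 "wedge is not anchored at a stereocenter; stereochemistry cannot be determined")
    }
  }
  for (ctr in centers) {
    p <- geom_parity(s, ctr, cls)
    if (!is.na(p) && p == 0)
      err <- add(err, "undeterminable_stereo", ctr,
                 "wedge layout is degenerate; the configuration cannot be determined")
    wedged <- !is.na(p) || length(wedges_at(s, ctr)) > 0L
    in_group <- any(vapply(s$stereo_groups, function(g) ctr %in% g$atoms, TRUE))
    has_either <- any(s$bonds$wedge == "either" &
                        (s$bonds$i == ctr | s$bonds$j == ctr))
    if (!wedged && !in_group && !has_either)
      warn <- add(warn, "unmarked_stereocenter", ctr,
                  "potential stereocenter without stereo annotation")
  }
  structure(list(errors = err, warnings = warn,
                 registrable = nrow(err) == 0L),
            class = "ucd_validation")
}

#' @export
print.ucd_validation <- function(x, ...) {
  cat(sprintf("<validation: %d error(s), %d warning(s)%s>\n",
              nrow(x$errors), nrow(x$warnings),
              if (x$registrable) ", registrable" else ""))
  if (nrow(x$errors)) print(x$errors)
  invisible(x)
}
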