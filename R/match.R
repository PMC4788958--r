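# Overlap computation: annotation-based automatic matching of two models'
# elements, manual post-editing, and conflict classification. Matching is a
# partial one-to-one map; ambiguity is never silently resolved - ambiguous
# elements stay unmatched and are surfaced for manual editing.

.match_entry <- function(class, id_a, id_b, source, confidence,
                         conflicts = NULL) {
  list(class = class, id_a = id_a, id_b = id_b, source = source,
       confidence = confidence,
       conflicts = conflicts %||% .empty_conflicts())
}

.empty_conflicts <- function() {
  data.frame(kind = character(0), detail = character(0), stringsAsFactors = FALSE)
}

.add_conflict <- function(df, kind, detail) {
  rbind(df, data.frame(kind = kind, detail = detail, stringsAsFactors = FALSE))
}

.new_match_set <- function(model_a, model_b, entries = list(),
                           candidate_conflicts = NULL) {
  ids_a <- model_element_ids(model_a)
  ids_b <- model_element_ids(model_b)
  matched_a <- split(vapply(entries, `[[`, character(1), "id_a"),
                     vapply(entries, `[[`, character(1), "class"))
  matched_b <- split(vapply(entries, `[[`, character(1), "id_b"),
                     vapply(entries, `[[`, character(1), "class"))
  un <- function(ids, matched) {
    lapply(setNames(names(ids), names(ids)), function(cl) {
      setdiff(ids[[cl]], matched[[cl]] %||% character(0))
    })
  }
  structure(list(entries = entries,
                 unmatched_a = un(ids_a, matched_a),
                 unmatched_b = un(ids_b, matched_b),
                 candidate_conflicts = candidate_conflicts %||%
                   data.frame(class = character(0), id_a = character(0),
                              id_b = character(0), kind = character(0),
                              detail = character(0), stringsAsFactors = FALSE),
                 model_a_id = model_a$model_id, model_b_id = model_b$model_id),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cls <- vapply(x$entries, `[[`, character(1), "class")
  cat(sprintf("<match_set> %s ~ %s: %d entries (%s)\n", x$model_a_id,
              x$model_b_id, length(x$entries),
              paste(sprintf("%s: %d", names(table(cls)), table(cls)),
                    collapse = ", ")))
  cat(sprintf("  unmatched A: %d, unmatched B: %d, flagged candidates: %d\n",
              sum(lengths(x$unmatched_a)), sum(lengths(x$unmatched_b)),
              nrow(x$candidate_conflicts)))
  invisible(x)
}

#' Automatic annotation-based matching of two models
#'
#' Computes the initial overlap of two models from the semantic identities of
#' their elements. Species and compartments match when their identities are
#' equal (URI sets equal when both annotated; structured names compatible, and
#' the sole criterion when annotations are missing). Reactions match when all
#' their reactant/product/modifier species match pairwise with equal
#' stoichiometries. Kinetic parameters are matched positionally through their
#' owning reactions, since they rarely carry database annotations. Elements
#' with several equally good candidates stay unmatched and are flagged
#' `annotation-name-disagreement` for manual post-editing.
#'
#' @param model_a,model_b [kinetic_model] objects.
#' @return a `match_set`.
#' @export
auto_match <- function(model_a, model_b) {
  entries <- list()
  cand_conf <- list()

  push_cc <- function(class, id_a, id_b, kind, detail) {
    cand_conf[[length(cand_conf) + 1L]] <<- data.frame(
      class = class, id_a = id_a, id_b = id_b, kind = kind, detail = detail,
      stringsAsFactors = FALSE)
  }

  # --- species and compartments: identity-based -----------------------------
  for (cls in c("compartment", "species")) {
    slot <- if (cls == "species") "species" else "compartments"
    els_a <- model_a[[slot]]
    els_b <- model_b[[slot]]
    if (length(els_a) == 0 || length(els_b) == 0) next
    ids_a <- lapply(els_a, extract_identity)
    ids_b <- lapply(els_b, extract_identity)
    cand <- matrix(FALSE, length(els_a), length(els_b),
                   dimnames = list(names(els_a), names(els_b)))
    for (i in names(els_a)) {
      for (j in names(els_b)) {
        cand[i, j] <- identity_equal(ids_a[[i]], ids_b[[j]])
      }
    }
    for (i in rownames(cand)) {
      js <- colnames(cand)[cand[i, ]]
      if (length(js) == 1L && sum(cand[, js]) == 1L) {
        both_annotated <- length(ids_a[[i]]$rdf_uris) > 0 &&
          length(ids_b[[js]]$rdf_uris) > 0
        entries[[length(entries) + 1L]] <- .match_entry(
          cls, i, js, "auto",
          if (both_annotated) "identical-annotation" else "identical-name")
      } else if (length(js) > 1L) {
        for (j in js) {
          push_cc(cls, i, j, "annotation-name-disagreement",
                  sprintf("'%s' matches %d candidates in model B", i, length(js)))
        }
      }
    }
    # B-side ambiguity (several A elements pointing at one B element)
    for (j in colnames(cand)) {
      is_ <- rownames(cand)[cand[, j]]
      if (length(is_) > 1L) {
        for (i in is_) {
          push_cc(cls, i, j, "annotation-name-disagreement",
                  sprintf("'%s' matches %d candidates in model A", j, length(is_)))
        }
      }
    }
  }

  sp_map <- .entry_map(entries, "species")

  # --- reactions: participant-structure based -------------------------------
  if (length(model_a$reactions) > 0 && length(model_b$reactions) > 0) {
    key_a <- lapply(model_a$reactions, .reaction_key, map = NULL)
    key_b <- lapply(model_b$reactions, .reaction_key, map = sp_map)
    cand <- matrix(FALSE, length(key_a), length(key_b),
                   dimnames = list(names(key_a), names(key_b)))
    for (i in names(key_a)) {
      for (j in names(key_b)) {
        cand[i, j] <- !is.null(key_b[[j]]) && identical(key_a[[i]], key_b[[j]])
      }
    }
    for (i in rownames(cand)) {
      js <- colnames(cand)[cand[i, ]]
      if (length(js) == 1L && sum(cand[, js]) == 1L) {
        entries[[length(entries) + 1L]] <- .match_entry(
          "reaction", i, js, "auto", "identical-annotation")
      } else if (length(js) > 1L) {
        for (j in js) {
          push_cc("reaction", i, j, "annotation-name-disagreement",
                  sprintf("reaction '%s' matches %d candidates", i, length(js)))
        }
      }
    }
  }

  # --- parameters: positional, through matched reactions --------------------
  rx_entries <- Filter(function(e) e$class == "reaction", entries)
  taken_a <- character(0); taken_b <- character(0)
  for (e in rx_entries) {
    pa <- .law_parameters(model_a, e$id_a)
    pb <- .law_parameters(model_b, e$id_b)
    if (length(pa) != length(pb)) next  # classified later as different-kinetics
    for (k in seq_along(pa)) {
      if (pa[k] %in% taken_a || pb[k] %in% taken_b) next
      entries[[length(entries) + 1L]] <- .match_entry(
        "parameter", pa[k], pb[k], "auto", "identical-annotation")
      taken_a <- c(taken_a, pa[k]); taken_b <- c(taken_b, pb[k])
    }
  }

  cc <- if (length(cand_conf) > 0) unique(do.call(rbind, cand_conf)) else NULL
  .new_match_set(model_a, model_b, entries, cc)
}

#' Participant fingerprint of a reaction, optionally translated through a
#' species match map (B id -> A id). NULL if a participant is unmatched.
#' @noRd
.reaction_key <- function(rx, map) {
  tr <- function(ids) {
    if (is.null(map)) return(ids)
    out <- map[ids]
    if (any(is.na(out))) return(NULL)
    unname(out)
  }
  r <- tr(rx$reactants$species); p <- tr(rx$products$species)
  m <- tr(rx$modifiers)
  if (is.null(r) || is.null(p) || is.null(m)) return(NULL)
  ord_r <- order(r); ord_p <- order(p)
  list(reactants = paste(r[ord_r], rx$reactants$stoichiometry[ord_r],
                         sep = "*", collapse = "|"),
       products = paste(p[ord_p], rx$products$stoichiometry[ord_p],
                        sep = "*", collapse = "|"),
       modifiers = paste(sort(m), collapse = "|"))
}

#' Parameters referenced by a reaction's kinetic law, in order of appearance
#' @noRd
.law_parameters <- function(model, rid) {
  rx <- model$reactions[[rid]]
  if (is.null(rx$kinetic_law)) return(character(0))
  syms <- expr_symbols(rx$kinetic_law)
  syms[syms %in% names(model$parameters)]
}

.entry_map <- function(entries, class) {
  e <- Filter(function(x) x$class == class, entries)
  setNames(vapply(e, `[[`, character(1), "id_a"),
           vapply(e, `[[`, character(1), "id_b"))
}

#' Manual post-editing of a match set
#'
#' Supported commands (each a list): `add-match` (pair two unmatched elements
#' of the same class), `remove-match` (return a pair to the unmatched lists),
#' `confirm-match` (mark an automatic entry user-asserted) and `flag-match`
#' (attach a conflict flag, e.g. `level-of-detail`, which is never assigned
#' automatically). Edits that would create a many-to-one match or pair
#' different element classes are rejected.
#'
#' @param matches a `match_set`.
#' @param edits list of edit commands, e.g.
#'   `list(list(action = "add-match", class = "species", id_a = "X", id_b = "Y"))`.
#' @param model_a,model_b the matched models (for invariant re-derivation).
#' @return the edited `match_set`.
#' @export
apply_edits <- function(matches, edits, model_a, model_b) {
  stopifnot(inherits(matches, "match_set"))
  entries <- matches$entries
  cc <- matches$candidate_conflicts
  find_entry <- function(class, id_a, id_b) {
    for (k in seq_along(entries)) {
      e <- entries[[k]]
      if (e$class == class && e$id_a == id_a && e$id_b == id_b) return(k)
    }
    NA_integer_
  }
  for (ed in edits) {
    act <- ed$action %||% stop("edit without action", call. = FALSE)
    cls <- ed$class
    if (act == "add-match") {
      # class check: both ids must exist as this class in their models
      model_element(model_a, cls, ed$id_a)
      model_element(model_b, cls, ed$id_b)
      for (e in entries) {
        if (e$class == cls && (e$id_a == ed$id_a || e$id_b == ed$id_b)) {
          stop(sprintf(
            "edit rejected: '%s' or '%s' is already matched (many-to-one)",
            ed$id_a, ed$id_b), call. = FALSE)
        }
      }
      entries[[length(entries) + 1L]] <- .match_entry(
        cls, ed$id_a, ed$id_b, "manual", "user-asserted")
    } else if (act == "remove-match") {
      k <- find_entry(cls, ed$id_a, ed$id_b)
      if (is.na(k)) {
        stop(sprintf("edit rejected: no %s match %s ~ %s", cls, ed$id_a, ed$id_b),
             call. = FALSE)
      }
      entries[[k]] <- NULL
    } else if (act == "confirm-match") {
      k <- find_entry(cls, ed$id_a, ed$id_b)
      if (is.na(k)) {
        stop(sprintf("edit rejected: no %s match %s ~ %s", cls, ed$id_a, ed$id_b),
             call. = FALSE)
      }
      entries[[k]]$confidence <- "user-asserted"
    } else if (act == "flag-match") {
      k <- find_entry(cls, ed$id_a, ed$id_b)
      if (is.na(k)) {
        stop(sprintf("edit rejected: no %s match %s ~ %s", cls, ed$id_a, ed$id_b),
             call. = FALSE)
      }
      entries[[k]]$conflicts <- .add_conflict(entries[[k]]$conflicts,
                                              ed$kind, ed$detail %||% "")
    } else {
      stop(sprintf("unknown edit action '%s'", act), call. = FALSE)
    }
  }
  out <- .new_match_set(model_a, model_b, entries, cc)
  out
}

#' Classify structural conflicts on a computed match set
#'
#' Adds conflict flags to matched entries and near-match candidates:
#' `different-compartment` (matched species living in unmatched
#' compartments), `different-kinetics` (matched reactions with symbolically
#' non-equivalent laws after id translation), `modifier-vs-reactant`
#' (unmatched reaction pairs producing the same products where a species
#' switches role), `modification-site` / `different-state` (URI-equal species
#' whose structured names differ in modifications). `level-of-detail` is
#' never assigned automatically; use [apply_edits()] with a `flag-match`
#' command.
#'
#' @param matches a `match_set` from [auto_match()].
#' @param model_a,model_b the matched models.
#' @return the annotated `match_set`.
#' @export
classify_conflicts <- function(matches, model_a, model_b) {
  stopifnot(inherits(matches, "match_set"))
  entries <- matches$entries
  comp_map <- .entry_map(entries, "compartment")  # B id -> A id
  sp_map <- .entry_map(entries, "species")
  cc <- matches$candidate_conflicts

  for (k in seq_along(entries)) {
    e <- entries[[k]]
    if (e$class == "species") {
      ca <- model_a$species[[e$id_a]]$compartment
      cb <- model_b$species[[e$id_b]]$compartment
      cb_in_a <- comp_map[cb]
      # flagged when B's compartment is unmatched, or matched to a different
      # compartment than the one the A species lives in
      if (is.na(cb_in_a) || cb_in_a != ca) {
        entries[[k]]$conflicts <- .add_conflict(
          e$conflicts, "different-compartment",
          sprintf("'%s' lives in '%s' (A) vs '%s' (B)", e$id_a, ca, cb))
      }
    } else if (e$class == "reaction") {
      flag <- .reaction_kinetics_conflict(entries, e, model_a, model_b, sp_map,
                                          comp_map)
      if (!is.null(flag)) {
        entries[[k]]$conflicts <- .add_conflict(e$conflicts,
                                                "different-kinetics", flag)
      }
    }
  }

  # near-matches among unmatched species: same URIs, different modifications
  for (i in matches$unmatched_a$species) {
    ia <- extract_identity(model_a$species[[i]])
    for (j in matches$unmatched_b$species) {
      kind <- identity_near_conflict(ia, extract_identity(model_b$species[[j]]))
      if (!is.na(kind)) {
        cc <- rbind(cc, data.frame(
          class = "species", id_a = i, id_b = j, kind = kind,
          detail = sprintf("URI-equal species '%s'/'%s' differ in modification state",
                           i, j),
          stringsAsFactors = FALSE))
      }
    }
  }

  # near-matches among unmatched reactions: same products, modifier/reactant swap
  for (i in matches$unmatched_a$reaction) {
    ra <- model_a$reactions[[i]]
    for (j in matches$unmatched_b$reaction) {
      rb <- model_b$reactions[[j]]
      kind <- .modifier_vs_reactant(ra, rb, sp_map)
      if (!is.na(kind)) {
        cc <- rbind(cc, data.frame(
          class = "reaction", id_a = i, id_b = j, kind = "modifier-vs-reactant",
          detail = kind, stringsAsFactors = FALSE))
      }
    }
  }

  matches$entries <- entries
  matches$candidate_conflicts <- unique(cc)
  matches
}

.reaction_kinetics_conflict <- function(entries, e, model_a, model_b, sp_map,
                                        comp_map) {
  la <- model_a$reactions[[e$id_a]]$kinetic_law
  lb <- model_b$reactions[[e$id_b]]$kinetic_law
  if (is.null(la) || is.null(lb)) return("missing kinetic law on one side")
  pa <- .law_parameters(model_a, e$id_a)
  pb <- .law_parameters(model_b, e$id_b)
  if (length(pa) != length(pb)) {
    return(sprintf("different parameter counts (%d vs %d)", length(pa), length(pb)))
  }
  map <- c(sp_map, comp_map, setNames(pa, pb))
  lb_tr <- substitute_symbols(lb, map[!is.na(map)])
  if (!expr_equivalent(la, lb_tr)) {
    return(sprintf("'%s' vs translated '%s'", deparse(la), deparse(lb_tr)))
  }
  NULL
}

.modifier_vs_reactant <- function(ra, rb, sp_map) {
  tr <- function(ids) {
    out <- sp_map[ids]
    if (any(is.na(out))) return(NULL)
    unname(out)
  }
  pb <- tr(rb$products$species)
  if (is.null(pb) || !setequal(ra$products$species, pb)) return(NA_character_)
  mb <- tr(rb$modifiers); rbs <- tr(rb$reactants$species)
  if (is.null(mb) || is.null(rbs)) return(NA_character_)
  swapped_ab <- intersect(ra$modifiers, rbs)
  swapped_ba <- intersect(ra$reactants$species, mb)
  sw <- union(swapped_ab, swapped_ba)
  if (length(sw) == 0) return(NA_character_)
  sprintf("species %s acts as modifier on one side and reactant on the other",
          paste(sprintf("'%s'", sw), collapse = ", "))
}
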