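#' Semantic hierarchy of clinical domains
#'
#' A hierarchy is a rooted tree of clinical-domain nodes. Three top-level
#' domains (Cognitive, Motor, Somatic) hang under a single implicit root;
#' terminal nodes ("leaf categories", e.g. Adaptability, Attention) are the
#' units under which harmonized questions are grouped. Node ids are full
#' slash-delimited paths (`"Cognitive/Behavioral/Emotional/Adaptability"`) so
#' that repeated labels -- catch-all leaves named after their own subgroup --
#' stay unambiguous.
#'
#' @param nodes A data frame with columns `id`, `name`, `parent` (`NA` for
#'   top-level nodes). Ids must be unique and every non-`NA` parent must be
#'   the id of another row.
#' @return A `rosetta_hierarchy` object: a list with a `nodes` tibble.
#' @examples
#' h <- hierarchy(data.frame(
#'   id = c("Motor", "Motor/Fine"),
#'   name = c("Motor", "Fine"),
#'   parent = c(NA, "Motor")
#' ))
#' hierarchy_leaves(h)
#' @export
hierarchy <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("id", "name", "parent")
  if (!all(required %in% names(nodes))) {
    parse_error(paste0(
      "hierarchy nodes need columns ",
      paste(required, collapse = ", ")
    ))
  }
  nodes <- dplyr::select(nodes, dplyr::all_of(required))
  nodes$id <- as.character(nodes$id)
  nodes$name <- as.character(nodes$name)
  nodes$parent <- as.character(nodes$parent)
  structure(list(nodes = nodes), class = "rosetta_hierarchy")
}

#' @export
print.rosetta_hierarchy <- function(x, ...) {
  lv <- hierarchy_leaves(x)
  cat(sprintf(
    "<rosetta_hierarchy> %d nodes, %d leaf categories, %d top-level domains\n",
    nrow(x$nodes), length(lv), sum(is.na(x$nodes$parent))
  ))
  invisible(x)
}

#' Leaf categories of a hierarchy
#'
#' @param h A `rosetta_hierarchy`.
#' @return Character vector of ids of nodes without children.
#' @export
hierarchy_leaves <- function(h) {
  stopifnot(inherits(h, "rosetta_hierarchy"))
  setdiff(h$nodes$id, h$nodes$parent[!is.na(h$nodes$parent)])
}

# Leaf names as they appear in the generation-1 mapping tables, grouped by
# the subgroup node they hang under. Catch-all leaves repeat their
# subgroup's name and are flagged so the default 57-leaf tree can omit the
# four that the narrative leaf counts do not include (the Social catch-all
# is part of the stated 19).
gen1_tree_spec <- function() {
  list(
    internal = tibble::tibble(
      id = c(
        "Cognitive", "Cognitive/Behavioral",
        "Cognitive/Behavioral/Emotional", "Cognitive/Behavioral/Sensory",
        "Cognitive/Behavioral/Social", "Cognitive/Language & Communication",
        "Cognitive/Executive Functioning", "Motor", "Motor/Gross", "Somatic"
      ),
      name = c(
        "Cognitive", "Behavioral", "Emotional", "Sensory", "Social",
        "Language & Communication", "Executive Functioning",
        "Motor", "Gross", "Somatic"
      ),
      parent = c(
        NA, "Cognitive", "Cognitive/Behavioral", "Cognitive/Behavioral",
        "Cognitive/Behavioral", "Cognitive", "Cognitive", NA, "Motor", NA
      )
    ),
    leaves = list(
      "Cognitive/Behavioral/Emotional" = c(
        "Adaptability", "Anger Control", "Anxiety", "Depression", "Mood",
        "Obsessive Compulsive", "Paranoia"
      ),
      "Cognitive/Behavioral/Sensory" = c("Disturbed", "Intrigued"),
      "Cognitive/Behavioral/Social" = c(
        "Aggression", "Atypicality", "Awareness", "Comforting", "Conduct",
        "Ego", "Eye Contact", "Group Play", "Imitation", "Joint Attention",
        "Leadership", "Maturity", "Reciprocal Interactions", "Relationships",
        "Shared Interests", "Smile", "Staring", "Withdrawal", "Social"
      ),
      "Cognitive/Language & Communication" = c(
        "Expressive", "Nonverbal", "Receptive", "Speech"
      ),
      "Cognitive/Executive Functioning" = c(
        "Arithmetic", "Attention", "Confusion", "Coping", "Fluency",
        "Hyperactivity", "Imagination", "Impulsivity", "Inhibitory Control",
        "Memory", "Patience", "Perseveration", "Planning", "Reasoning"
      ),
      "Motor" = "Fine",
      # The gross-motor subgroup splits into two further leaves whose labels
      # are fixture metadata, not published semantics.
      "Motor/Gross" = c("Locomotion", "Coordination"),
      "Somatic" = c(
        "Dermatologic", "Fatigue", "Gastrointestinal", "Illness",
        "Neurologic", "Sleep", "Vision", "Weight"
      )
    ),
    catch_alls = c(
      "Cognitive/Behavioral/Emotional", "Cognitive/Behavioral/Sensory",
      "Cognitive/Executive Functioning", "Somatic"
    )
  )
}

#' Default generation-1 hierarchy
#'
#' Builds the packaged generation-1 tree: Cognitive (Behavioral with
#' Emotional, Sensory and Social subgroups; Language & Communication;
#' Executive Functioning), Motor (Fine; Gross with two sub-leaves) and
#' Somatic, for a total of 57 leaf categories.
#'
#' The published per-leaf fusion table additionally lists subgroup-level
#' catch-all rows for Emotional, Sensory, Executive Functioning and Somatic
#' (the Social catch-all is already one of Social's 19 leaves). Setting
#' `include_catch_alls = TRUE` adds those four leaves (61 leaves), which is
#' the reading needed to attach every question of the generation-1 manifest
#' to a leaf.
#'
#' @param include_catch_alls Add the four subgroup-level catch-all leaves.
#' @return A `rosetta_hierarchy`.
#' @examples
#' h <- build_default_hierarchy()
#' length(hierarchy_leaves(h)) # 57
#' @export
build_default_hierarchy <- function(include_catch_alls = FALSE) {
  spec <- gen1_tree_spec()
  leaf_rows <- purrr::imap_dfr(spec$leaves, function(nms, parent) {
    tibble::tibble(id = paste(parent, nms, sep = "/"), name = nms, parent = parent)
  })
  if (include_catch_alls) {
    ca <- tibble::tibble(
      id = paste(spec$catch_alls, vapply(strsplit(spec$catch_alls, "/"),
        function(p) p[[length(p)]], ""
      ), sep = "/"),
      name = vapply(strsplit(spec$catch_alls, "/"), function(p) p[[length(p)]], ""),
      parent = spec$catch_alls
    )
    leaf_rows <- dplyr::bind_rows(leaf_rows, ca)
  }
  hierarchy(dplyr::bind_rows(spec$internal, leaf_rows))
}

#' Validate a hierarchy
#'
#' Checks the structural invariants of the tree: unique ids, no orphan
#' nodes (every non-root parent id resolves), no cycles, every node
#' reachable from a root. Returns a report rather than signalling, so that
#' malformed-but-parseable inputs can be inspected; parse failures in
#' [read_hierarchy()] signal a `rosetta_parse_error` instead.
#'
#' @param h A `rosetta_hierarchy`.
#' @return A tibble with columns `rule`, `where`, `message`; zero rows iff
#'   the hierarchy is valid.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "rosetta_hierarchy"))
  nodes <- h$nodes
  out <- no_violations()

  dup <- unique(nodes$id[duplicated(nodes$id)])
  for (id in dup) {
    out <- dplyr::bind_rows(out, violation("duplicate id", id, "node id occurs more than once"))
  }

  known <- nodes$id
  orphan <- nodes$id[!is.na(nodes$parent) & !(nodes$parent %in% known)]
  for (id in orphan) {
    out <- dplyr::bind_rows(out, violation("orphan node", id, "parent id does not exist"))
  }

  if (!any(is.na(nodes$parent)) && nrow(nodes) > 0) {
    out <- dplyr::bind_rows(out, violation("no root", "<hierarchy>", "no top-level node"))
  }

  # walk to a root from every node; revisiting a node on one walk is a cycle
  parent_of <- setNames(nodes$parent, nodes$id)
  for (id in setdiff(nodes$id, c(dup, orphan))) {
    seen <- character()
    cur <- id
    while (!is.na(cur) && cur %in% names(parent_of)) {
      if (cur %in% seen) {
        out <- dplyr::bind_rows(out, violation("cycle", id, "parent links form a cycle"))
        break
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  out
}

resolve_leaf <- function(h, leaf_id) {
  leaves <- hierarchy_leaves(h)
  if (leaf_id %in% h$nodes$id) {
    return(leaf_id)
  }
  hits <- leaves[h$nodes$name[match(leaves, h$nodes$id)] == leaf_id]
  if (length(hits) == 1L) {
    return(hits)
  }
  if (length(hits) > 1L) {
    abort(sprintf("leaf name '%s' is ambiguous; use a full path id", leaf_id))
  }
  abort(sprintf("unknown node '%s'", leaf_id))
}

#' Path from root to a leaf
#'
#' @param h A `rosetta_hierarchy`.
#' @param leaf_id A leaf id (full path) or an unambiguous leaf name.
#' @return Character vector of node names from the top-level domain down to
#'   the leaf.
#' @examples
#' leaf_path(build_default_hierarchy(), "Attention")
#' @export
leaf_path <- function(h, leaf_id) {
  stopifnot(inherits(h, "rosetta_hierarchy"))
  id <- resolve_leaf(h, leaf_id)
  if (!(id %in% hierarchy_leaves(h))) {
    abort(sprintf("'%s' is an internal node, not a leaf", id))
  }
  parent_of <- setNames(h$nodes$parent, h$nodes$id)
  name_of <- setNames(h$nodes$name, h$nodes$id)
  path <- character()
  cur <- id
  while (!is.na(cur)) {
    path <- c(name_of[[cur]], path)
    cur <- parent_of[[cur]]
  }
  path
}

# Question-id token for a leaf: path names with spaces/& removed, joined by
# "_" ("Cognitive/Language & Communication/Speech" ->
# "Cognitive_LanguageCommunication_Speech").
leaf_token <- function(h, leaf_id) {
  path <- leaf_path(h, leaf_id)
  paste(gsub("[^A-Za-z0-9]", "", path), collapse = "_")
}

#' Read / write a hierarchy file
#'
#' Hierarchies are stored as structured text with a `format` header field
#' (`"json"` or `"yaml"`) and a `nodes` array of `{id, name, parent}`
#' records. [read_hierarchy()] sniffs JSON vs YAML from the content when the
#' header is absent.
#'
#' @param path File path.
#' @param h A `rosetta_hierarchy`.
#' @param format `"json"` or `"yaml"`.
#' @return [read_hierarchy()] returns a `rosetta_hierarchy`;
#'   [write_hierarchy()] returns `path` invisibly.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("no such file: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- tryCatch(
    {
      if (grepl("^\\s*\\{", txt)) {
        jsonlite::fromJSON(txt, simplifyDataFrame = TRUE)
      } else {
        yaml::yaml.load(txt)
      }
    },
    error = function(e) parse_error(sprintf("cannot parse hierarchy file: %s", conditionMessage(e)))
  )
  if (is.null(doc$nodes)) parse_error("hierarchy file has no 'nodes' section")
  nodes <- doc$nodes
  if (!is.data.frame(nodes)) {
    nodes <- purrr::map_dfr(nodes, function(n) {
      tibble::tibble(
        id = n$id %||% NA_character_,
        name = n$name %||% NA_character_,
        parent = n$parent %||% NA_character_
      )
    })
  }
  if (any(is.na(nodes$id))) parse_error("hierarchy node without an id")
  hierarchy(nodes)
}

#' @rdname read_hierarchy
#' @export
write_hierarchy <- function(h, path, format = c("json", "yaml")) {
  stopifnot(inherits(h, "rosetta_hierarchy"))
  format <- match.arg(format)
  doc <- list(format = format, nodes = h$nodes)
  if (format == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, na = "null", pretty = TRUE)
  } else {
    nodes <- purrr::pmap(h$nodes, function(id, name, parent) {
      n <- list(id = id, name = name)
      if (!is.na(parent)) n$parent <- parent
      n
    })
    yaml::write_yaml(list(format = format, nodes = nodes), path)
  }
  invisible(path)
}
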