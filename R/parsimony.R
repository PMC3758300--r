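# Equal-cost (Fitch) small parsimony on a fixed rooted phylogeny, as a
# unit-cost Sankoff dynamic programme: exact for polytomies, multistate
# alphabets and a constrained root state.

#' Read a rooted tree from a newick file
#'
#' Branch lengths are ignored; polytomies are permitted; leaf labels must
#' be unique.
#'
#' @param path newick file (or a newick string).
#' @return an \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(
    if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path),
    error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: no tree parsed")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Write a tree to newick
#' @param tree a \code{phylo}.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# unit-cost Sankoff tables over a rooted phylo.
# states: named character vector over tips; NA or "?" = unknown.
# Returns list(cost = nodes x states matrix, alphabet, root).
sankoff_tables <- function(tree, states, alphabet = NULL, derived_state = NULL) {
  tips <- tree$tip.label
  miss <- setdiff(tips, names(states))
  if (length(miss)) stop("missing states for leaves: ", paste(miss, collapse = ", "))
  st <- as.character(states[tips])
  st[st == "?"] <- NA_character_
  alphabet <- sort(unique(c(alphabet, st[!is.na(st)], derived_state)))
  bad <- setdiff(st[!is.na(st)], alphabet)
  if (length(bad)) stop("state(s) outside alphabet: ", paste(bad, collapse = ", "))
  ntip <- length(tips)
  nnode <- tree$Nnode
  S <- length(alphabet)
  cost <- matrix(0, nrow = ntip + nnode, ncol = S,
                 dimnames = list(NULL, alphabet))
  for (i in seq_len(ntip)) {
    if (!is.na(st[i])) {
      cost[i, ] <- Inf
      cost[i, st[i]] <- 0
    }
  }
  # origin objective: minimum number of edges entering derived_state among
  # labelings achieving the subtree cost
  orig <- matrix(0, nrow = ntip + nnode, ncol = S, dimnames = list(NULL, alphabet))
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(edges))) {
    parent <- edges[r, 1L]; child <- edges[r, 2L]
    # per parent-state contribution of this child
    add_c <- numeric(S); add_o <- numeric(S)
    for (si in seq_len(S)) {
      ccost <- cost[child, ] + (alphabet != alphabet[si])
      corig <- orig[child, ]
      if (!is.null(derived_state)) {
        corig <- corig + (alphabet == derived_state & alphabet[si] != derived_state)
      }
      best <- min(ccost)
      add_c[si] <- best
      add_o[si] <- min(corig[ccost == best])
    }
    cost[parent, ] <- cost[parent, ] + add_c
    orig[parent, ] <- orig[parent, ] + add_o
  }
  root <- ntip + 1L
  list(cost = cost, orig = orig, alphabet = alphabet, root = root)
}

#' Minimum number of state changes on a fixed tree (Fitch parsimony)
#'
#' Equal change costs; polytomies allowed; unknown leaf states ("?" or NA)
#' are free.  With \code{fixed_root_state} the root label is constrained.
#'
#' @param tree a rooted \code{phylo}.
#' @param states named character vector of leaf states.
#' @param fixed_root_state optional root state.
#' @return integer: the parsimony length.
#' @export
fitch_length <- function(tree, states, fixed_root_state = NULL) {
  tb <- sankoff_tables(tree, states, alphabet = fixed_root_state)
  v <- if (is.null(fixed_root_state)) {
    min(tb$cost[tb$root, ])
  } else {
    tb$cost[tb$root, fixed_root_state]
  }
  as.integer(v)
}

#' Minimum number of independent origins of a derived state
#'
#' The minimum, over all most-parsimonious labelings (with the root fixed
#' to the ancestral state), of the number of branches on which the
#' character transitions into \code{derived_state}.
#'
#' @param tree a rooted \code{phylo}.
#' @param states named character vector of leaf states.
#' @param derived_state the state whose origins are counted.
#' @param fixed_root_state the ancestral root state (default: treat the
#'   root as unconstrained minimum-cost).
#' @return integer; 0 when the derived state is absent from all leaves.
#'   The attribute \code{parsimony_length} carries the tree length used.
#' @export
count_independent_origins <- function(tree, states, derived_state,
                                      fixed_root_state = NULL) {
  st <- as.character(states)
  if (!any(st == derived_state, na.rm = TRUE)) return(0L)
  tb <- sankoff_tables(tree, states, alphabet = fixed_root_state,
                       derived_state = derived_state)
  if (is.null(fixed_root_state)) {
    best <- min(tb$cost[tb$root, ])
    sel <- tb$cost[tb$root, ] == best
    # a root already in the derived state is itself one origin
    o <- tb$orig[tb$root, ] + (tb$alphabet == derived_state)
    res <- as.integer(min(o[sel]))
  } else {
    best <- tb$cost[tb$root, fixed_root_state]
    res <- as.integer(tb$orig[tb$root, fixed_root_state] +
                        (fixed_root_state == derived_state))
  }
  attr(res, "parsimony_length") <- as.integer(best)
  res
}

#' Read a taxon-by-character state table
#'
#' TSV with a \code{taxon} column and one column per character.
#'
#' @param path TSV file.
#' @return data.frame with taxa as row names.
#' @export
read_character_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    comment.char = "#")
  if (!"taxon" %in% names(tab)) stop("character matrix needs a 'taxon' column")
  if (anyDuplicated(tab$taxon)) stop("duplicate taxa in character matrix")
  rownames(tab) <- tab$taxon
  tab$taxon <- NULL
  tab
}

#' Map characters onto a tree: lengths and independent origins
#'
#' Convenience wrapper running \code{\link{fitch_length}} and
#' \code{\link{count_independent_origins}} for each character column.
#'
#' @param tree a rooted \code{phylo}.
#' @param chars data.frame from \code{\link{read_character_matrix}}.
#' @param derived_state state counted as derived (default "1").
#' @param fixed_root_state root constraint (default "0", the ancestral
#'   absent state, matching a gain-then-degradation narrative).
#' @return data.frame with columns character, length, origins.
#' @export
map_characters <- function(tree, chars, derived_state = "1",
                           fixed_root_state = "0") {
  rows <- lapply(names(chars), function(cn) {
    st <- setNames(chars[[cn]], rownames(chars))
    data.frame(character = cn,
               length = fitch_length(tree, st, fixed_root_state),
               origins = as.integer(count_independent_origins(
                 tree, st, derived_state, fixed_root_state)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
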