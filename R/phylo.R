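#' Parse a dated (ultrametric) Newick tree
#'
#' Reads a chronogram whose branch lengths are in million years (Mya) and
#' converts path lengths to node ages: a node's age is the tree height
#' minus its distance from the root, so extant tips sit at age 0 and the
#' root at the tree height. Optionally attaches discrete tip character
#' states (environmental sex determination \code{esd}, female heterogamety
#' \code{zw}, or \code{unknown}).
#'
#' @param source Newick string or path to a Newick file.
#' @param tip_states optional named character vector (tip label -> state)
#'   or data frame with columns \code{tip_id}, \code{state}. Tips missing
#'   from the map get \code{unknown}.
#' @param states the character's state space, default
#'   \code{c("esd", "zw")}.
#' @param tolerance relative tolerance on tip-depth equality for the
#'   ultrametricity check, default 1e-6.
#' @return An object of class \code{"dated_tree"}: list with \code{phylo}
#'   (the \pkg{ape} tree), \code{node_ages} (ages in Mya for all node
#'   numbers, tips first), \code{tip_states}, \code{states}.
#' @examples
#' tr <- parse_dated_newick("((A:120,B:120):80,C:200);")
#' tr$node_ages  # tips 0, internal node 120, root 200
#' @export
parse_dated_newick <- function(source, tip_states = NULL,
                               states = c("esd", "zw"), tolerance = 1e-6) {
  phy <- if (grepl("\\(", source)) ape::read.tree(text = source)
         else ape::read.tree(source)
  if (is.null(phy)) stop("could not parse Newick input")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (any(is.na(phy$tip.label)) || any(!nzchar(phy$tip.label)))
    stop("unlabeled tip(s)")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  n_tip <- length(phy$tip.label)
  if (n_tip > 2L && !ape::is.binary(phy))
    stop("tree must be bifurcating")
  depth <- ape::node.depth.edgelength(phy)   # distance from root
  height <- max(depth[seq_len(n_tip)])
  tip_depths <- depth[seq_len(n_tip)]
  if (height > 0 && any(abs(tip_depths - height) > tolerance * height))
    stop("tree is not ultrametric: tip depths differ beyond tolerance")
  ages <- height - depth
  ages[seq_len(n_tip)] <- 0
  st <- stats::setNames(rep("unknown", n_tip), phy$tip.label)
  if (!is.null(tip_states)) {
    if (is.data.frame(tip_states))
      tip_states <- stats::setNames(as.character(tip_states$state),
                                    tip_states$tip_id)
    extra <- setdiff(names(tip_states), phy$tip.label)
    if (length(extra))
      stop("tip state(s) for unknown tip(s): ", paste(extra, collapse = ", "))
    bad <- setdiff(unique(tip_states), c(states, "unknown"))
    if (length(bad))
      stop("tip state(s) outside the state space: ",
           paste(bad, collapse = ", "))
    st[names(tip_states)] <- tip_states
  }
  structure(list(phylo = phy, node_ages = ages, tip_states = st,
                 states = states),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  n_tip <- length(x$phylo$tip.label)
  cat("Dated tree:", n_tip, "tips, root age",
      format(max(x$node_ages), digits = 4), "Mya\n")
  cat("Tip states:", paste(sprintf("%s=%d", names(table(x$tip_states)),
                                   table(x$tip_states)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Canonical Newick serialization of a dated tree
#'
#' @param tree a \code{\link{parse_dated_newick}} object.
#' @return Newick string with branch lengths in Mya.
#' @export
as_newick <- function(tree) {
  ape::write.tree(tree$phylo)
}

#' Read tip character states from CSV
#'
#' Columns \code{tip_id}, \code{state}.
#'
#' @param path CSV file.
#' @return Named character vector tip -> state.
#' @export
read_tip_states <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tip_id", "state") %in% names(x)))
    stop("tip-state file needs columns tip_id, state")
  stats::setNames(as.character(x$state), x$tip_id)
}

#' Parsimony ancestral-state reconstruction on a dated tree
#'
#' \code{method = "fitch"} (default) computes standard Fitch
#' small-parsimony state sets by postorder traversal: a node's set is the
#' intersection of its children's sets when nonempty, otherwise their
#' union (counting one change). Tips with state \code{unknown} contribute
#' the full state space and never force changes. The parsimony score is
#' the number of union events — the minimum number of state changes on
#' the tree.
#'
#' \code{method = "dollo"} reconstructs under the constraint that the
#' derived state arises exactly once and can only be lost thereafter
#' (appropriate for characters hard to regain, such as differentiated sex
#' chromosomes): every node inside the most recent common ancestor of the
#' derived tips that retains at least one derived descendant is assigned
#' the derived state, all other nodes the ancestral state(s).
#'
#' @param tree a \code{\link{parse_dated_newick}} object.
#' @param tip_states optional override of the tree's tip states.
#' @param method \code{"fitch"} or \code{"dollo"}.
#' @param derived the derived state for Dollo, default \code{"zw"}.
#' @return List with \code{node_sets} (list over node numbers, tips
#'   included, each a character vector of states), \code{score} (minimum
#'   number of changes; for Dollo, under the single-gain constraint) and
#'   \code{method}.
#' @export
fitch_ancestral <- function(tree, tip_states = NULL,
                            method = c("fitch", "dollo"), derived = "zw") {
  method <- match.arg(method)
  phy <- tree$phylo
  states <- tree$states
  st <- tree$tip_states
  if (!is.null(tip_states)) st[names(tip_states)] <- tip_states
  n_tip <- length(phy$tip.label)
  known <- st[st != "unknown"]
  if (length(known) == 0L) stop("all tips have unknown state")
  n_node <- max(phy$edge, n_tip)
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip))
    sets[[i]] <- if (st[phy$tip.label[i]] == "unknown") states
                 else st[phy$tip.label[i]]
  if (method == "fitch") {
    po <- ape::reorder.phylo(phy, "postorder")
    score <- 0L
    for (i in seq_len(nrow(po$edge))) {
      p <- po$edge[i, 1L]; k <- po$edge[i, 2L]
      if (is.null(sets[[p]])) {
        sets[[p]] <- sets[[k]]
      } else {
        inter <- intersect(sets[[p]], sets[[k]])
        if (length(inter)) sets[[p]] <- inter
        else { sets[[p]] <- union(sets[[p]], sets[[k]]); score <- score + 1L }
      }
    }
  } else {
    der_tips <- which(phy$tip.label %in% names(known)[known == derived])
    if (length(der_tips) == 0L)
      stop("derived state absent from tips; Dollo undefined")
    anc <- setdiff(states, derived)
    desc <- descendant_tips(phy)
    mrca_nd <- if (length(der_tips) == 1L) der_tips else
      ape::getMRCA(phy, der_tips)
    inside <- c(mrca_nd, unlist(phylo_descendants(phy, mrca_nd)))
    for (nd in seq_len(n_node)) {
      if (nd <= n_tip) next
      has_der <- length(intersect(desc[[nd]], der_tips)) > 0L
      sets[[nd]] <- if (nd %in% inside && has_der) derived else anc
    }
    # score: one gain + one loss per maximal ancestral subtree inside
    state_of <- function(nd) {
      s <- sets[[nd]]
      if (length(s) == 1L) s else NA_character_
    }
    score <- 0L
    for (i in seq_len(nrow(phy$edge))) {
      p <- state_of(phy$edge[i, 1L]); c_ <- state_of(phy$edge[i, 2L])
      if (!is.na(p) && !is.na(c_) && p != c_) score <- score + 1L
    }
    if (mrca_nd == n_tip + 1L) score <- score + 1L  # gain predates the root
  }
  list(node_sets = sets, score = score, method = method)
}

# tip numbers descending from each node (tips descend from themselves)
descendant_tips <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- max(phy$edge, n_tip)
  out <- vector("list", n_node)
  for (i in seq_len(n_tip)) out[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; k <- po$edge[i, 2L]
    out[[p]] <- c(out[[p]], out[[k]])
  }
  out
}

# all descendant node numbers (internal and tips) of a node
phylo_descendants <- function(phy, node) {
  out <- integer(0)
  frontier <- node
  while (length(frontier)) {
    kids <- phy$edge[phy$edge[, 1L] %in% frontier, 2L]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Bracket the origin age of a derived character state
#'
#' Finds the maximal clade whose reconstructed crown state set is exactly
#' the derived state and brackets the trait's origin between that clade's
#' crown age (the character was certainly present in the clade's common
#' ancestor: lower bound) and its stem age — the split from the sister
#' lineage lacking the state (the character cannot predate the lineage:
#' upper bound).
#'
#' @param tree a \code{\link{parse_dated_newick}} object with tip states.
#' @param derived the derived state, default \code{"zw"}.
#' @param method reconstruction method, see \code{\link{fitch_ancestral}}.
#' @return An object of class \code{"origin_interval"}: list with
#'   \code{state}, \code{min_age}, \code{max_age} (Mya), \code{crown_node},
#'   \code{stem_node} (ape node numbers), \code{n_derived_tips}.
#' @examples
#' tr <- parse_dated_newick("((A:120,B:120):80,C:200);",
#'                          tip_states = c(A = "zw", B = "zw", C = "esd"))
#' origin_interval(tr)  # bracket (120, 200) Mya
#' @export
origin_interval <- function(tree, derived = "zw",
                            method = c("fitch", "dollo")) {
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  if (!any(tree$tip_states == derived))
    stop("derived state '", derived, "' absent from tips")
  rec <- fitch_ancestral(tree, method = method, derived = derived)
  is_pure <- vapply(rec$node_sets, function(s)
    length(s) == 1L && s == derived, TRUE)
  parent_of <- function(nd) {
    p <- phy$edge[phy$edge[, 2L] == nd, 1L]
    if (length(p)) p else NA_integer_
  }
  root <- n_tip + 1L
  if (is_pure[root])
    stop("derived state reconstructed at the root: no bracket ",
         "(outgroup also carries '", derived, "')")
  cand <- which(is_pure &
                  vapply(seq_along(is_pure), function(nd) {
                    p <- parent_of(nd)
                    !is.na(p) && !is_pure[p]
                  }, TRUE))
  if (length(cand) == 0L)
    stop("no maximal clade fixed for '", derived, "'")
  if (length(cand) > 1L)
    stop("multiple maximal clades carry '", derived,
         "'; the origin bracket is not unique")
  crown <- cand
  stem <- parent_of(crown)
  if (crown <= n_tip)
    zdose_warn("SINGLE_LINEAGE", paste(
      "derived state confined to a single tip;",
      "crown age degenerates to 0"))
  out <- structure(
    list(state = derived, min_age = tree$node_ages[crown],
         max_age = tree$node_ages[stem], crown_node = crown,
         stem_node = stem,
         n_derived_tips = sum(tree$tip_states == derived)),
    class = "origin_interval")
  out
}

#' @export
print.origin_interval <- function(x, ...) {
  cat(sprintf(
    "Origin of state '%s': between %.4g Mya (crown) and %.4g Mya (stem)\n",
    x$state, x$min_age, x$max_age))
  cat(sprintf("  crown node %d, stem node %d, %d derived tip(s)\n",
              x$crown_node, x$stem_node, x$n_derived_tips))
  invisible(x)
}
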