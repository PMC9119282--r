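# Canonical Newick / extended-Newick serialization.
#
# Children are ordered by (smallest descendant leaf label, expanded canonical
# subtree form, reticulation flag); a reticulation's child subtree is printed
# at its first-printed occurrence and referenced as #H<k> afterwards, with
# tags numbered in print order. parse(serialize(x)) round-trips to an
# isomorphic object with an identical canonical string.

#' Serialize a gene tree or phylogenetic network to canonical (extended) Newick
#'
#' @param x a `gene_tree` or `phylo_network`
#' @param ... unused
#' @return a single string ending in `;`
#' @export
serialize_newick <- function(x, ...) UseMethod("serialize_newick")

#' @export
serialize_newick.gene_tree <- function(x, ...) {
  canon <- character(x$n)
  minlab <- character(x$n)
  for (v in x$postorder) {
    if (x$is_leaf[v]) {
      canon[v] <- x$label[v]
      minlab[v] <- x$label[v]
    } else {
      ch <- x$children[[v]]
      ord <- order(minlab[ch], canon[ch])
      canon[v] <- paste0("(", paste(canon[ch][ord], collapse = ","), ")")
      minlab[v] <- min(minlab[ch])
    }
  }
  paste0(canon[x$root], ";")
}

#' @export
serialize_newick.phylo_network <- function(x, ...) {
  live_rev <- rev(x$topo)
  canon <- character(x$n)
  minlab <- character(x$n)
  is_ret <- x$kind == "reticulation"
  for (v in live_rev) {
    if (x$outdeg[v] == 0L) {
      canon[v] <- x$label[v]
      minlab[v] <- x$label[v]
    } else {
      ch <- x$children[[v]]
      ord <- order(minlab[ch], canon[ch], is_ret[ch])
      kc <- canon[ch][ord]
      canon[v] <- if (is_ret[v] && length(ch) == 1L) paste0("~", kc)
        else paste0("(", paste(kc, collapse = ","), ")")
      minlab[v] <- min(minlab[ch])
    }
  }
  tagno <- new.env(parent = emptyenv())
  tagno$k <- 0L
  tagno$tag <- rep(NA_integer_, x$n)
  emit <- function(v) {
    if (x$outdeg[v] == 0L) return(x$label[v])
    if (is_ret[v]) {
      if (is.na(tagno$tag[v])) {
        tagno$k <- tagno$k + 1L
        tagno$tag[v] <- tagno$k
        kids <- paste(vapply(ordered_children(v), emit, character(1)),
                      collapse = ",")
        return(paste0("(", kids, ")#H", tagno$tag[v]))
      }
      return(paste0("#H", tagno$tag[v]))
    }
    kids <- paste(vapply(ordered_children(v), emit, character(1)),
                  collapse = ",")
    paste0("(", kids, ")")
  }
  ordered_children <- function(v) {
    ch <- x$children[[v]]
    ch[order(minlab[ch], canon[ch], is_ret[ch])]
  }
  paste0(emit(x$root), ";")
}
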