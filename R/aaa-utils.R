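# Internal helpers shared across the package.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("odt_input_error", "error", "condition")))
}

stop_class <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("odt_class_error", "error", "condition")))
}

stop_cap <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("odt_cap_error", "error", "condition")))
}

# Postorder of a rooted tree/forest given a children list (children before
# parents, deterministic for a fixed children order).
post_order <- function(children, root) {
  s1 <- root
  s2 <- integer(0)
  while (length(s1)) {
    v <- s1[length(s1)]
    s1 <- s1[-length(s1)]
    s2 <- c(s2, v)
    s1 <- c(s1, children[[v]])
  }
  rev(s2)
}

# Deterministic topological order of a DAG (ancestors first, smallest node id
# among the currently available nodes first). `use` restricts to live nodes.
topo_order <- function(children, use) {
  n <- length(children)
  indeg <- integer(n)
  for (v in which(use)) for (w in children[[v]]) indeg[w] <- indeg[w] + 1L
  avail <- which(use & indeg == 0L)
  out <- integer(0)
  indeg[!use] <- NA_integer_
  while (length(avail)) {
    v <- min(avail)
    avail <- avail[avail != v]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(out) != sum(use)) stop_input("graph contains a directed cycle")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
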