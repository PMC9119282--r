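# Shared recursive-descent parser for Newick / extended Newick (#H tags).
# Produces a raw node table that parse_gene_tree() / parse_enewick() refine.

parse_newick_raw <- function(text) {
  s <- gsub("[[:space:]]+", "", paste(text, collapse = ""))
  if (!nzchar(s)) stop_input("empty Newick input")
  n_max <- nchar(s)
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$label <- character(0)
  env$tag <- character(0)
  env$children <- list()

  peek <- function() if (env$pos > n_max) "" else substr(s, env$pos, env$pos)
  advance <- function() env$pos <- env$pos + 1L
  new_node <- function() {
    id <- length(env$label) + 1L
    env$label[id] <- NA_character_
    env$tag[id] <- NA_character_
    env$children[[id]] <- integer(0)
    id
  }
  read_name <- function() {
    start <- env$pos
    while (env$pos <= n_max &&
           !substr(s, env$pos, env$pos) %in% c("(", ")", ",", ";", ":"))
      advance()
    substr(s, start, env$pos - 1L)
  }
  skip_branch_length <- function() {
    if (peek() == ":") {
      advance()
      read_name()
    }
  }
  set_name <- function(id, nm) {
    if (!nzchar(nm)) return(invisible())
    if (grepl("#", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "#", fixed = TRUE)[[1]]
      tag <- paste(parts[-1], collapse = "#")
      if (!grepl("^H?[0-9]+$", tag))
        stop_input("malformed hybrid tag '#%s' at position %d", tag, env$pos)
      env$tag[id] <- sub("^H?", "H", tag)
      if (nzchar(parts[1])) env$label[id] <- parts[1]
    } else {
      env$label[id] <- nm
    }
  }
  parse_subtree <- function() {
    if (peek() == "(") {
      advance()
      id <- new_node()
      kids <- integer(0)
      repeat {
        kids <- c(kids, parse_subtree())
        if (peek() == ",") {
          advance()
          next
        }
        if (peek() == ")") {
          advance()
          break
        }
        stop_input("syntax error at position %d: expected ',' or ')'", env$pos)
      }
      env$children[[id]] <- kids
      set_name(id, read_name())
    } else {
      nm <- read_name()
      if (!nzchar(nm))
        stop_input("syntax error at position %d: expected a label", env$pos)
      id <- new_node()
      set_name(id, nm)
    }
    skip_branch_length()
    id
  }

  root <- parse_subtree()
  if (peek() != ";")
    stop_input("syntax error at position %d: expected ';'", env$pos)
  list(label = env$label, tag = env$tag, children = env$children, root = root)
}
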