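#' @title KEGG module definitions: parsing and completeness
#'
#' @description
#' KEGG module definitions are boolean expressions over KEGG Orthology (KO)
#' identifiers, organised into sequential "blocks" (reaction steps). The
#' grammar implemented here follows KEGG conventions:
#'
#' * a space separates sequential blocks (all required),
#' * a comma separates alternatives (any one suffices),
#' * `+` joins obligatory subunits of a complex (all required),
#' * a `-`-prefixed component is optional and excluded from requirements,
#' * parentheses group arbitrarily; a space inside parentheses is a
#'   conjunction within the enclosing block,
#' * `--` is a missing-step placeholder, treated as an always-absent leaf,
#' * `M#####` leaves reference other modules and must be resolved via a
#'   mapping at evaluation time.
#'
#' Completeness of a module in a genome is the fraction of top-level blocks
#' whose expression is satisfied by the genome's KO set.
#'
#' @name kegg-modules
NULL

# ---- tokenizer -------------------------------------------------------------

kegg_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == " ") {
      # collapse runs of spaces into one separator token
      j <- i
      while (j <= n && chars[j] == " ") j <- j + 1L
      push("space", " ", i)
      i <- j
    } else if (ch %in% c("(", ")", ",", "+")) {
      push(ch, ch, i)
      i <- i + 1L
    } else if (ch == "-") {
      if (i < n && chars[i + 1L] == "-") {
        push("gap", "--", i)
        i <- i + 2L
      } else {
        push("-", "-", i)
        i <- i + 1L
      }
    } else if (grepl("[A-Za-z0-9_.]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_.]", chars[j])) j <- j + 1L
      push("ident", paste(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
    } else {
      abort(sprintf("module definition parse error at position %d: unexpected character '%s'", i, ch))
    }
  }
  tokens
}

# ---- recursive-descent parser ---------------------------------------------
#
# expr  := alt
# alt   := seq (',' seq)*
# seq   := term (' ' term)*
# term  := ['-'] factor (('+'|'-') factor)*
# factor:= KO | M##### | '--' | '(' alt ')'

kegg_node <- function(kind, children = list(), id = NULL) {
  structure(list(kind = kind, children = children, id = id),
            class = "kegg_node")
}

parse_module_tokens <- function(tokens, text) {
  state <- new.env(parent = emptyenv())
  state$i <- 1L
  peek <- function() if (state$i <= length(tokens)) tokens[[state$i]] else NULL
  advance <- function() {
    tok <- tokens[[state$i]]
    state$i <- state$i + 1L
    tok
  }
  fail <- function(msg, tok = peek()) {
    pos <- if (is.null(tok)) nchar(text) + 1L else tok$pos
    abort(sprintf("module definition parse error at position %d: %s", pos, msg))
  }

  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) fail("expected a KO identifier or '('")
    if (tok$type == "ident") {
      advance()
      if (grepl("^K\\d{5}$", tok$value)) {
        kegg_node("ko", id = tok$value)
      } else if (grepl("^M\\d{5}$", tok$value)) {
        kegg_node("module_ref", id = tok$value)
      } else {
        fail(sprintf("identifier '%s' is neither a KO (K#####) nor a module reference (M#####)", tok$value), tok)
      }
    } else if (tok$type == "gap") {
      advance()
      kegg_node("gap")
    } else if (tok$type == "(") {
      advance()
      inner <- parse_alt()
      closing <- peek()
      if (is.null(closing) || closing$type != ")") fail("unbalanced parentheses: expected ')'")
      advance()
      inner
    } else {
      fail(sprintf("unexpected '%s'", tok$value), tok)
    }
  }

  parse_term <- function() {
    prefix_optional <- FALSE
    tok <- peek()
    if (!is.null(tok) && tok$type == "-") {
      advance()
      prefix_optional <- TRUE
    }
    parts <- list(parse_factor())
    optional_flags <- FALSE
    repeat {
      tok <- peek()
      if (is.null(tok) || !(tok$type %in% c("+", "-"))) break
      op <- advance()
      parts[[length(parts) + 1L]] <- parse_factor()
      optional_flags <- c(optional_flags, op$type == "-")
    }
    node <- if (length(parts) == 1L) {
      parts[[1L]]
    } else {
      children <- purrr::map2(parts, optional_flags, function(p, opt) {
        if (opt) kegg_node("optional", children = list(p)) else p
      })
      kegg_node("complex", children = children)
    }
    if (prefix_optional) kegg_node("optional", children = list(node)) else node
  }

  parse_seq <- function() {
    terms <- list(parse_term())
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != "space") break
      # a space is a separator only if something parseable follows
      nxt <- if (state$i + 1L <= length(tokens)) tokens[[state$i + 1L]] else NULL
      if (is.null(nxt) || nxt$type %in% c(")", ",")) {
        advance()
        next
      }
      advance()
      terms[[length(terms) + 1L]] <- parse_term()
    }
    if (length(terms) == 1L) terms[[1L]] else kegg_node("seq", children = terms)
  }

  parse_alt <- function() {
    alts <- list(parse_seq())
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != ",") break
      advance()
      alts[[length(alts) + 1L]] <- parse_seq()
    }
    if (length(alts) == 1L) alts[[1L]] else kegg_node("alt", children = alts)
  }

  # tolerate leading/trailing spaces
  if (!is.null(peek()) && peek()$type == "space") advance()
  root <- parse_alt()
  leftover <- peek()
  if (!is.null(leftover)) fail(sprintf("dangling '%s'", leftover$value), leftover)
  root
}

#' Parse a KEGG module definition string
#'
#' @param text The definition string, e.g. `"(K00001,K00002) K00003+K00004"`.
#' @param module_id Optional module identifier (e.g. `"M00123"`).
#' @param name Optional human-readable module name.
#' @return An object of class `kegg_module` holding the expression tree.
#'   Malformed definitions (unbalanced parentheses, dangling operators,
#'   non-KO identifiers) raise an error naming the offending position.
#' @seealso [module_completeness()], [block_present()], [format_module()]
#' @examples
#' m <- parse_module_definition("K90101 (K90102,K90103) K90104+K90105")
#' length(module_blocks(m)) # 3 blocks
#' @export
parse_module_definition <- function(text, module_id = NA_character_, name = NA_character_) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort("parse_module_definition(): 'text' must be a non-empty string")
  }
  tokens <- kegg_tokenize(text)
  root <- parse_module_tokens(tokens, text)
  structure(
    list(module_id = module_id, name = name, text = text, root = root),
    class = "kegg_module"
  )
}

#' @export
print.kegg_module <- function(x, ...) {
  id <- if (is.na(x$module_id)) "<unnamed>" else x$module_id
  cat(sprintf("<kegg_module %s: %d block(s)>\n", id, length(module_blocks(x))))
  cat(format_module(x), "\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

serialize_node <- function(node, parent = "top") {
  out <- switch(node$kind,
    ko = node$id,
    module_ref = node$id,
    gap = "--",
    optional = {
      inner <- serialize_node(node$children[[1L]], parent = "complex")
      paste0("-", inner)
    },
    complex = {
      parts <- purrr::map_chr(node$children, function(ch) {
        if (ch$kind == "optional") {
          serialize_node(ch, parent = "complex")
        } else {
          paste0("+", serialize_node(ch, parent = "complex"))
        }
      })
      sub("^\\+", "", paste(parts, collapse = ""))
    },
    seq = paste(purrr::map_chr(node$children, serialize_node, parent = "seq"),
                collapse = " "),
    alt = paste(purrr::map_chr(node$children, serialize_node, parent = "alt"),
                collapse = ","),
    abort(sprintf("unknown node kind '%s'", node$kind))
  )
  needs_parens <- switch(node$kind,
    alt = parent %in% c("seq", "complex"),
    seq = parent %in% c("alt", "complex"),
    FALSE
  )
  if (needs_parens) paste0("(", out, ")") else out
}

#' Serialize a parsed module back to definition text
#'
#' `parse_module_definition(format_module(m))` reproduces the same expression
#' tree (serialization is a fixed point of the parse/serialize pair).
#'
#' @param module A `kegg_module`.
#' @return A definition string.
#' @export
format_module <- function(module) {
  stopifnot(inherits(module, "kegg_module"))
  serialize_node(module$root)
}

# ---- evaluation ------------------------------------------------------------

resolve_module_ref <- function(id, kos, resolve) {
  if (is.null(resolve) || is.null(resolve[[id]])) {
    abort(sprintf("unresolved nested module reference '%s': supply a resolution mapping via 'resolve'", id))
  }
  entry <- resolve[[id]]
  if (is.logical(entry) && length(entry) == 1L) return(entry)
  if (inherits(entry, "kegg_module")) {
    return(module_completeness(entry, kos, resolve = resolve)$complete)
  }
  if (is.character(entry) && length(entry) == 1L && !grepl("^K\\d{5}$", entry)) {
    sub <- parse_module_definition(entry, module_id = id)
    return(module_completeness(sub, kos, resolve = resolve)$complete)
  }
  # character vector of KOs: the referenced module stands for their conjunction
  all(entry %in% kos)
}

node_present <- function(node, kos, resolve = NULL) {
  switch(node$kind,
    ko = node$id %in% kos,
    module_ref = resolve_module_ref(node$id, kos, resolve),
    gap = FALSE,
    optional = TRUE,
    alt = any(purrr::map_lgl(node$children, node_present, kos = kos, resolve = resolve)),
    seq = all(purrr::map_lgl(node$children, node_present, kos = kos, resolve = resolve)),
    complex = {
      required <- purrr::keep(node$children, ~ .x$kind != "optional")
      all(purrr::map_lgl(required, node_present, kos = kos, resolve = resolve))
    },
    abort(sprintf("unknown node kind '%s'", node$kind))
  )
}

#' Top-level blocks of a module
#'
#' The top-level, space-separated units of the definition; `-`-prefixed
#' (optional) top-level units are excluded, as they carry no requirement.
#'
#' @param module A `kegg_module`.
#' @return A list of expression-tree nodes, one per block.
#' @export
module_blocks <- function(module) {
  stopifnot(inherits(module, "kegg_module"))
  root <- module$root
  blocks <- if (root$kind == "seq") root$children else list(root)
  purrr::keep(blocks, ~ .x$kind != "optional")
}

#' Evaluate one block against a KO set
#'
#' Recursive evaluation: a sequence requires all children, an alternative any
#' child, a complex all non-optional subunits; optional components are always
#' satisfied; a KO leaf tests set membership; `--` is never satisfied.
#'
#' @param block A node as returned by [module_blocks()].
#' @param kos Character vector of KO identifiers present in the genome.
#' @param resolve Optional named list resolving `M#####` references to a
#'   definition string, a parsed `kegg_module`, a KO vector (conjunction), or
#'   a logical. Unresolved references raise an error.
#' @return Logical flag.
#' @export
block_present <- function(block, kos, resolve = NULL) {
  node_present(block, kos, resolve = resolve)
}

# collect KO leaves; optional subtrees excluded unless include_optional
module_kos <- function(node, include_optional = FALSE) {
  if (inherits(node, "kegg_module")) node <- node$root
  switch(node$kind,
    ko = node$id,
    module_ref = character(),
    gap = character(),
    optional = if (include_optional) {
      module_kos(node$children[[1L]], include_optional)
    } else {
      character()
    },
    unique(unlist(purrr::map(node$children, module_kos,
                             include_optional = include_optional)))
  )
}

#' Block-based completeness of a module in a genome
#'
#' @param module A `kegg_module`.
#' @param kos Character vector of KO identifiers present in the genome.
#' @inheritParams block_present
#' @return A one-row tibble: `module_id`, `n_blocks`, `n_present_blocks`,
#'   `fraction` (present blocks / total blocks), `complete`
#'   (`fraction == 1`), and `missing_kos` (list column: non-optional KOs of
#'   unsatisfied blocks absent from the genome).
#' @examples
#' m <- parse_module_definition("K90101 K90102", module_id = "Mx")
#' module_completeness(m, "K90101")$fraction # 0.5
#' @export
module_completeness <- function(module, kos, resolve = NULL) {
  stopifnot(inherits(module, "kegg_module"))
  blocks <- module_blocks(module)
  if (length(blocks) == 0L) {
    abort(sprintf("module %s has no non-optional blocks; completeness is undefined",
                  module$module_id))
  }
  present <- purrr::map_lgl(blocks, block_present, kos = kos, resolve = resolve)
  missing <- sort(unique(unlist(purrr::map(blocks[!present], module_kos))))
  missing <- setdiff(missing, kos)
  tibble(
    module_id = module$module_id,
    n_blocks = length(blocks),
    n_present_blocks = sum(present),
    fraction = sum(present) / length(blocks),
    complete = all(present),
    missing_kos = list(missing)
  )
}

#' Can one missing gene rescue the module?
#'
#' A module is "partially complete, allowing one missing gene" when it is not
#' complete as annotated but the addition of a single KO would complete it.
#' The rule is applied literally at the gene level (one KO), not per block.
#'
#' @inheritParams module_completeness
#' @return A one-row tibble with `partial_one_missing` (flag) and
#'   `rescuing_ko` (the alphabetically first KO whose addition completes the
#'   module, or `NA`). Complete modules return `FALSE`/`NA`.
#' @export
partial_one_missing <- function(module, kos, resolve = NULL) {
  base <- module_completeness(module, kos, resolve = resolve)
  if (base$complete) {
    return(tibble(module_id = module$module_id,
                  partial_one_missing = FALSE, rescuing_ko = NA_character_))
  }
  candidates <- sort(setdiff(module_kos(module$root), kos))
  for (ko in candidates) {
    if (module_completeness(module, c(kos, ko), resolve = resolve)$complete) {
      return(tibble(module_id = module$module_id,
                    partial_one_missing = TRUE, rescuing_ko = ko))
    }
  }
  tibble(module_id = module$module_id,
         partial_one_missing = FALSE, rescuing_ko = NA_character_)
}

#' Completeness of many modules in many genomes
#'
#' Convenience wrapper evaluating a module table against a long KO table.
#'
#' @param modules A tibble with columns `module_id`, `definition`, and
#'   optionally `name`.
#' @param ko_table A tibble with columns `genome_id` and `ko`.
#' @inheritParams block_present
#' @param one_missing Also evaluate the one-missing-gene rescue rule.
#' @return A tibble with one row per genome x module.
#' @export
completeness_table <- function(modules, ko_table, resolve = NULL, one_missing = TRUE) {
  stopifnot(is.data.frame(modules), all(c("module_id", "definition") %in% names(modules)),
            is.data.frame(ko_table), all(c("genome_id", "ko") %in% names(ko_table)))
  parsed <- purrr::pmap(list(modules$definition, modules$module_id), function(def, id) {
    parse_module_definition(def, module_id = id)
  })
  genomes <- sort(unique(ko_table$genome_id))
  ko_sets <- split(ko_table$ko, ko_table$genome_id)
  out <- purrr::map(genomes, function(g) {
    kos <- ko_sets[[g]]
    rows <- purrr::map(parsed, function(m) {
      res <- module_completeness(m, kos, resolve = resolve)
      if (one_missing) {
        res <- dplyr::bind_cols(res,
          partial_one_missing(m, kos, resolve = resolve)["partial_one_missing"])
      }
      res
    })
    dplyr::bind_cols(tibble(genome_id = g), dplyr::bind_rows(rows))
  })
  dplyr::bind_rows(out)
}
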