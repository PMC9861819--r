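# Minimal reverse-mode automatic differentiation over R arrays.
#
# A node is an environment holding a value, its parent nodes and a backward
# closure mapping the node's output gradient to a list of parent gradients.
# Nodes are created in forward order, so creation index gives a topological
# order for the backward sweep.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L
.ag$grad_enabled <- TRUE

ag_grad_enabled <- function() .ag$grad_enabled

with_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  force(expr)
}

ag_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  if (.ag$grad_enabled) {
    node$parents <- parents
    node$backward <- backward
  } else {
    node$parents <- list()
    node$backward <- NULL
  }
  node$grad <- NULL
  .ag$counter <- .ag$counter + 1L
  node$idx <- .ag$counter
  class(node) <- "ag_node"
  node
}

# Leaf with no history; used for inputs and parameters.
ag_leaf <- function(value) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- list()
  node$backward <- NULL
  node$grad <- NULL
  .ag$counter <- .ag$counter + 1L
  node$idx <- .ag$counter
  class(node) <- "ag_node"
  node
}

is_ag_node <- function(x) inherits(x, "ag_node")

as_ag_node <- function(x) if (is_ag_node(x)) x else ag_leaf(x)

node_value <- function(x) if (is_ag_node(x)) x$value else x

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(node)
}

# Backpropagate from a scalar (or seeded) root through the tape.
ag_backward <- function(root, seed = 1) {
  stopifnot(is_ag_node(root))
  # collect the reachable subgraph
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$idx)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$idx, numeric(1)), decreasing = TRUE)
  nodes <- nodes[ord]
  root$grad <- seed * array(1, dim = dim(root$value) %||% 1)
  if (is.null(dim(root$value))) root$grad <- rep(seed, length(root$value))
  for (n in nodes) {
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    for (i in seq_along(n$parents)) {
      if (!is.null(gs[[i]])) ag_accum(n$parents[[i]], gs[[i]])
    }
    n$grad <- NULL  # free intermediate gradients early
  }
  invisible(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
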