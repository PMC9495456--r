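# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every differentiable quantity is an `ag_node`: an environment holding the
# value (`v`), an accumulated gradient (`grad`), the parent nodes and a
# backward closure that routes the node's gradient into its parents. Ops
# build the tape only while gradients are enabled, so inference-time
# forwards carry no memory overhead.

.ls_state <- new.env(parent = emptyenv())
.ls_state$grad_enabled <- TRUE
.ls_state$visit <- 0L

ag_grad_enabled <- function() .ls_state$grad_enabled

#' Evaluate an expression with gradient taping disabled
#'
#' Used for inference forwards so that no intermediate buffers are retained.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_no_grad <- function(expr) {
  old <- .ls_state$grad_enabled
  .ls_state$grad_enabled <- FALSE
  on.exit(.ls_state$grad_enabled <- old)
  expr
}

new_ag_node <- function(value, parents = list(), backward = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$param <- param
  e$vis <- 0L
  class(e) <- "ag_node"
  e
}

ag_const <- function(x) new_ag_node(x)

ag_param <- function(x) new_ag_node(x, param = TRUE)

is_ag_node <- function(x) inherits(x, "ag_node")

as_ag_node <- function(x) if (is_ag_node(x)) x else ag_const(x)

node_value <- function(x) if (is_ag_node(x)) x$v else x

# TRUE when the node sits on a live tape (is a parameter or has parents)
node_tracked <- function(x) is_ag_node(x) && (x$param || length(x$parents) > 0L)

# Create an op output node; drops the tape when gradients are off or no
# parent is tracked.
ag_op <- function(value, parents, backward) {
  if (ag_grad_enabled() && any(vapply(parents, node_tracked, logical(1)))) {
    new_ag_node(value, parents = parents, backward = backward)
  } else {
    new_ag_node(value)
  }
}

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse-topological traversal (iterative; the nets are deep).
backprop <- function(root, seed_grad = 1) {
  .ls_state$visit <- .ls_state$visit + 1L
  tag <- .ls_state$visit
  order <- vector("list", 0L)
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    if (top$stage == 1L) {
      if (nd$vis == tag) next
      nd$vis <- tag
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (is_ag_node(p) && p$vis != tag && length(p$parents) > 0L) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      order[[length(order) + 1L]] <- nd
    }
  }
  # `order` is child-after-parents; walk it reversed
  root$grad <- seed_grad
  for (i in rev(seq_along(order))) {
    nd <- order[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd)
  }
  invisible(root)
}

# ---- parameter bookkeeping ---------------------------------------------

#' Collect trainable parameter nodes from a (nested) module structure
#' @param x a module, list of modules, or parameter node.
#' @return flat list of `ag_node` parameters.
#' @keywords internal
collect_params <- function(x) {
  out <- list()
  walk <- function(o) {
    if (is_ag_node(o)) {
      if (o$param) out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' One SGD-with-momentum update over a list of parameter nodes
#' @keywords internal
sgd_step <- function(params, lr, momentum = 0.9) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$mom)) p$mom <- p$grad else p$mom <- momentum * p$mom + p$grad
    p$v <- p$v - lr * p$mom
  }
  invisible(NULL)
}

n_params <- function(x) sum(vapply(collect_params(x), function(p) length(p$v), numeric(1)))
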