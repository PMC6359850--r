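#' Serialize and deserialize a Logistic Model Tree
#'
#' `serialize_lmt()` renders a trained model as a JSON document (schema
#' version 1) containing the class order, feature names, boosting iteration
#' count, and the full tree with per-class leaf coefficient vectors.
#' `deserialize_lmt()` restores a model that produces identical predictions.
#'
#' @param model An `lmt_model`.
#' @param path Optional file path; when given the document is written there.
#' @return `serialize_lmt()` returns the JSON text (invisibly when `path` is
#'   given); `deserialize_lmt()` returns an `lmt_model`.
#' @examples
#' d <- tibble::tibble(x = c(rnorm(20, -2), rnorm(20, 2)),
#'                     label = rep(c("LR", "PO"), each = 20))
#' m <- train_lmt(d, features = "x", control = lmt_control(prune = FALSE, seed = 1))
#' m2 <- deserialize_lmt(serialize_lmt(m))
#' identical(predict(m, d), predict(m2, d))
#' @export
serialize_lmt <- function(model, path = NULL) {
  if (!inherits(model, "lmt_model")) abort("`model` must be an lmt_model")
  node_to_list <- function(node) {
    if (node$type == "leaf") {
      list(
        type = "leaf", n = node$n, depth = node$depth,
        gamma = lapply(seq_len(ncol(node$gamma)), function(j) unname(node$gamma[, j]))
      )
    } else {
      list(
        type = "split", n = node$n, depth = node$depth,
        feature = node$feature, threshold = node$threshold,
        left = node_to_list(node$left), right = node_to_list(node$right)
      )
    }
  }
  doc <- list(
    schema = "gaitphase-lmt", schema_version = 1L,
    class_order = model$class_order,
    feature_names = model$feature_names,
    n_boost_iter = model$n_boost_iter,
    tree_size = model$tree_size, n_leaves = model$n_leaves,
    n_train = model$n_train,
    tree = node_to_list(model$root)
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' @rdname serialize_lmt
#' @param text JSON text, or the path of a file containing it.
#' @export
deserialize_lmt <- function(text) {
  if (length(text) == 1 && !grepl("^\\s*\\{", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  if (!nzchar(trimws(paste(text, collapse = "")))) {
    abort("parse error: empty model document")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) abort(paste0("parse error in model document: ", conditionMessage(e)))
  )
  required <- c("schema", "schema_version", "class_order", "feature_names", "tree")
  missing_k <- setdiff(required, names(doc))
  if (length(missing_k) > 0) {
    abort(paste0("parse error at document root: missing field(s) ", paste(missing_k, collapse = ", ")))
  }
  if (!identical(doc$schema, "gaitphase-lmt")) {
    abort("parse error at document root: not a gaitphase LMT document")
  }
  classes <- unlist(doc$class_order)
  features <- unlist(doc$feature_names)
  p <- length(features)

  list_to_node <- function(nd, path, depth) {
    if (is.null(nd$type)) abort(paste0("parse error at ", path, ": missing node type"))
    if (nd$type == "leaf") {
      if (is.null(nd$gamma) || length(nd$gamma) != length(classes)) {
        abort(paste0("parse error at ", path, ": leaf must hold one coefficient vector per class"))
      }
      gamma <- vapply(nd$gamma, function(g) as.numeric(unlist(g)), numeric(p + 1))
      dimnames(gamma) <- list(c("(intercept)", features), classes)
      .lmt_leaf(as.integer(nd$n %||% NA), as.integer(nd$err %||% 0), gamma,
        as.integer(nd$depth %||% depth), NULL
      )
    } else if (nd$type == "split") {
      if (is.null(nd$feature) || is.null(nd$threshold)) {
        abort(paste0("parse error at ", path, ": split node needs feature and threshold"))
      }
      fi <- as.integer(nd$feature)
      if (fi < 1 || fi > p) abort(paste0("parse error at ", path, ": feature index out of range"))
      list(
        type = "split", n = as.integer(nd$n %||% NA), err = 0L,
        gamma = NULL, depth = as.integer(nd$depth %||% depth),
        class_counts = NULL,
        feature = fi, threshold = as.numeric(nd$threshold),
        left = list_to_node(nd$left, paste0(path, "/left"), depth + 1),
        right = list_to_node(nd$right, paste0(path, "/right"), depth + 1)
      )
    } else {
      abort(paste0("parse error at ", path, ": unknown node type `", nd$type, "`"))
    }
  }
  root <- list_to_node(doc$tree, "tree", 0L)
  cnt <- .lmt_count(root)
  structure(
    list(
      root = root, class_order = classes, feature_names = features,
      n_boost_iter = as.integer(doc$n_boost_iter %||% NA),
      control = NULL,
      tree_size = unname(cnt["size"]), n_leaves = unname(cnt["leaves"]),
      n_train = as.integer(doc$n_train %||% NA)
    ),
    class = "lmt_model"
  )
}
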