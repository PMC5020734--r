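#' Life-cycle constraint graph
#'
#' The set of allowed transition arcs that constrains the inverse solution.
#' Each arc is a (target class, source class) pair with a demographic role:
#' \describe{
#'   \item{stasis}{remaining in the same class, diagonal entries (i, i)}
#'   \item{growth}{advancing one class, subdiagonal entries (i+1, i)}
#'   \item{shrinkage}{partial-mortality retreat one class, superdiagonal
#'     entries (i-1, i)}
#'   \item{fertility}{recruitment into class 1 from a larger class, first-row
#'     entries (1, j), j > 1}
#' }
#' Matrix entries off the declared arcs are constrained to zero when a
#' transition matrix is estimated or validated against the structure.
#'
#' @param arcs A data.frame with integer columns `target`, `source` and a
#'   character column `role` (one of stasis, growth, shrinkage, fertility).
#' @param n_classes Number of size classes the arcs refer to.
#' @return An object of class `life_cycle_structure`.
#' @seealso [porites_structure()] for the default massive-coral graph.
#' @export
life_cycle_structure <- function(arcs, n_classes) {
  stopifnot(is.data.frame(arcs), all(c("target", "source", "role") %in% names(arcs)))
  arcs <- data.frame(target = as.integer(arcs$target),
                     source = as.integer(arcs$source),
                     role = as.character(arcs$role),
                     stringsAsFactors = FALSE)
  k <- as.integer(n_classes)
  if (k < 2L) stop("need at least 2 classes")
  if (any(arcs$target < 1L | arcs$target > k | arcs$source < 1L | arcs$source > k)) {
    stop("arc indices outside 1..", k)
  }
  ok <- c("stasis", "growth", "shrinkage", "fertility")
  if (any(!arcs$role %in% ok)) {
    stop("unknown role(s): ", paste(setdiff(arcs$role, ok), collapse = ", "))
  }
  bad_role <- with(arcs,
    (role == "stasis" & target != source) |
    (role == "growth" & target != source + 1L) |
    (role == "shrinkage" & target != source - 1L) |
    (role == "fertility" & (target != 1L | source <= 1L)))
  if (any(bad_role)) {
    stop("arc/role mismatch at row(s): ", paste(which(bad_role), collapse = ", "))
  }
  if (anyDuplicated(arcs[c("target", "source")])) {
    stop("duplicate arcs are not allowed")
  }
  arcs <- arcs[order(arcs$source, arcs$target), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(arcs = arcs, n_classes = k), class = "life_cycle_structure")
}

#' Default life-cycle graph for massive Porites
#'
#' Stasis loops in every class, growth by one class only, shrinkage of the
#' largest class into the second largest, and recruitment (fertility) into
#' class 1 from the two largest classes. For five classes this gives 12 free
#' parameters.
#'
#' @param k Number of size classes (default 5).
#' @return A [life_cycle_structure()].
#' @export
porites_structure <- function(k = 5L) {
  k <- as.integer(k)
  if (k < 3L) stop("the default graph needs at least 3 classes")
  arcs <- rbind(
    data.frame(target = 1:k, source = 1:k, role = "stasis"),
    data.frame(target = 2:k, source = 1:(k - 1L), role = "growth"),
    data.frame(target = k - 1L, source = k, role = "shrinkage"),
    data.frame(target = c(1L, 1L), source = c(k - 1L, k), role = "fertility")
  )
  life_cycle_structure(arcs, k)
}

#' Stasis-only structure (diagonal matrix), mainly for tests and degenerate
#' checks.
#' @param k Number of classes.
#' @return A [life_cycle_structure()].
#' @export
stasis_structure <- function(k = 5L) {
  life_cycle_structure(
    data.frame(target = 1:k, source = 1:k, role = "stasis"), k)
}

#' @export
print.life_cycle_structure <- function(x, ...) {
  cat("Life-cycle structure:", x$n_classes, "classes,",
      nrow(x$arcs), "arcs\n")
  print(table(x$arcs$role))
  invisible(x)
}

n_arcs <- function(structure) nrow(structure$arcs)

# 0/1 pattern matrix of allowed arcs (target x source)
structure_pattern <- function(structure) {
  k <- structure$n_classes
  P <- matrix(0, k, k)
  P[cbind(structure$arcs$target, structure$arcs$source)] <- 1
  P
}

is_survival_role <- function(role) role %in% c("stasis", "growth", "shrinkage")

#' Read / write a life-cycle structure as YAML
#'
#' The file is a list of arcs, each with `target`, `source` and `role`
#' fields, plus a top-level `n_classes`.
#'
#' @param path File path.
#' @param structure A [life_cycle_structure()].
#' @return `read_structure_yaml` returns a [life_cycle_structure()];
#'   `write_structure_yaml` returns `path` invisibly.
#' @export
read_structure_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  arcs <- do.call(rbind, lapply(y$arcs, function(a) {
    data.frame(target = a$target, source = a$source, role = a$role)
  }))
  life_cycle_structure(arcs, y$n_classes)
}

#' @rdname read_structure_yaml
#' @export
write_structure_yaml <- function(structure, path) {
  y <- list(
    n_classes = structure$n_classes,
    arcs = lapply(seq_len(nrow(structure$arcs)), function(i) {
      as.list(structure$arcs[i, ])
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
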