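# Semantic output module: maps the decoder's feature vector onto the nutrient
# simplex, plus the machinery that turns a class label into a reference
# nutrient vector via a food-composition table.

#' Tracked nutrient classes
#'
#' The six tracked nutrients plus an explicit remainder class. Published
#' composition tables rarely sum to 100% of the reference intake, so the
#' remainder class absorbs the shortfall and lets a softmax simplex represent
#' the row faithfully.
#' @return Character vector of class names.
#' @export
nutrient_classes <- function() {
  c("protein", "fat", "fiber", "carbohydrate", "minerals", "water", "remainder")
}

.head_forward <- function(f, weights, mode = "eval", dropout = 0.3) {
  drop1 <- drop2 <- NULL
  x <- f
  if (mode == "train" && dropout > 0) {
    drop1 <- (stats::runif(length(x)) >= dropout) / (1 - dropout)
    x <- x * drop1
  }
  z1 <- as.numeric(weights$W1 %*% x + weights$b1)
  a1 <- gelu(z1)
  a1d <- a1
  if (mode == "train" && dropout > 0) {
    drop2 <- (stats::runif(length(a1)) >= dropout) / (1 - dropout)
    a1d <- a1 * drop2
  }
  logits <- as.numeric(weights$W2 %*% a1d + weights$b2)
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  list(p = p, logits = logits, a1 = a1, a1d = a1d, z1 = z1, x = x,
       drop1 = drop1, drop2 = drop2)
}

.head_backward <- function(dp, cache, weights) {
  p <- cache$p
  dlogits <- p * (dp - sum(dp * p))
  dW2 <- tcrossprod(dlogits, cache$a1d)
  db2 <- dlogits
  da1d <- as.numeric(crossprod(weights$W2, dlogits))
  da1 <- if (is.null(cache$drop2)) da1d else da1d * cache$drop2
  dz1 <- da1 * gelu_grad(cache$z1)
  dW1 <- tcrossprod(dz1, cache$x)
  db1 <- dz1
  dx <- as.numeric(crossprod(weights$W1, dz1))
  if (!is.null(cache$drop1)) dx <- dx * cache$drop1
  list(df = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Map a feature vector to a nutrient distribution
#'
#' Two fully connected layers with a GELU hidden activation and train-only
#' dropout, finishing in a softmax over the nutrient classes, so the output
#' always lies on the probability simplex.
#'
#' @param v Numeric feature vector.
#' @param weights List with `W1` (hidden x d), `b1`, `W2` (classes x hidden),
#'   `b2`.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @param dropout Dropout rate used in train mode.
#' @return A named numeric vector summing to 1.
#' @export
semantic_output <- function(v, weights, mode = "eval", dropout = 0.3) {
  if (length(v) != ncol(weights$W1))
    dimension_error(sprintf("feature width %d does not match head input %d",
                            length(v), ncol(weights$W1)))
  p <- .head_forward(as.numeric(v), weights, mode, dropout)$p
  stats::setNames(p, rownames(weights$W2) %||% nutrient_classes()[seq_along(p)])
}

#' Load a food-composition table
#'
#' Reads a CSV (columns `food,protein,fat,fiber,carbohydrate,minerals,water`,
#' in percent-of-reference-intake units) or an equivalent JSON file, and
#' renormalises every row to the unit simplex: the tracked columns are
#' divided by 100 and an explicit `remainder` class absorbs any shortfall
#' from 100%.
#'
#' @param path Path to the CSV or JSON table.
#' @return A tibble of class `nutrient_table` with a `food` column and one
#'   column per [nutrient_classes()] entry, each row summing to 1.
#' @export
load_nutrient_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("nutrient table not found: %s", path))
  cols <- setdiff(nutrient_classes(), "remainder")
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch({
    if (ext == "json") {
      j <- jsonlite::fromJSON(path)
      as.data.frame(j, stringsAsFactors = FALSE)
    } else {
      utils::read.csv(path, stringsAsFactors = FALSE)
    }
  }, error = function(e) validation_error(sprintf("cannot parse '%s': %s", path, conditionMessage(e))))
  if (nrow(raw) == 0L) validation_error(sprintf("nutrient table '%s' is empty", path))
  if (!"food" %in% names(raw)) validation_error("nutrient table needs a 'food' column")
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0L)
    validation_error(paste("nutrient table missing columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(raw$food))
    validation_error(paste("duplicate food names:",
                           paste(unique(raw$food[duplicated(raw$food)]), collapse = ", ")))
  for (cc in cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0L)
      validation_error(sprintf("row '%s': column '%s' is negative or unparseable",
                               raw$food[bad[1L]], cc))
    raw[[cc]] <- v
  }
  frac <- as.matrix(raw[, cols]) / 100
  tracked <- rowSums(frac)
  over <- which(tracked > 1 + 1e-9)
  if (length(over) > 0L) {
    # rows exceeding 100% are scaled onto the simplex with zero remainder
    frac[over, ] <- frac[over, , drop = FALSE] / tracked[over]
    tracked[over] <- 1
  }
  out <- tibble::tibble(food = raw$food)
  for (i in seq_along(cols)) out[[cols[i]]] <- unname(frac[, i])
  out$remainder <- unname(pmax(0, 1 - tracked))
  class(out) <- c("nutrient_table", class(out))
  out
}

#' Look up the nutrient vector for a class label
#'
#' @param label A class label present in `mapping`.
#' @param mapping Named list or vector mapping labels to food names.
#' @param table A `nutrient_table` from [load_nutrient_table()] (or built in
#'   code with the same columns).
#' @return A named numeric nutrient vector (sums to 1).
#' @export
map_label <- function(label, mapping, table) {
  key <- as.character(label)
  if (!key %in% names(mapping))
    validation_error(sprintf("label '%s' has no food mapping", key))
  food <- mapping[[key]]
  row <- which(table$food == food)
  if (length(row) != 1L)
    validation_error(sprintf("food '%s' (label '%s') not found in the nutrient table", food, key))
  v <- as.numeric(table[row, nutrient_classes()])
  stats::setNames(v, nutrient_classes())
}
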