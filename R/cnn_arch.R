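# Architecture definitions for the 3Conv-6Conv model family, in both the
# channels-x-time (2D) and scalp-grid (3D) input modes.  Each layer carries
# the display token its table row prints; the instantiated layer sequence of
# a built model serializes back to exactly these tokens (audited in tests).

times_sign <- "×"

conv2_layer <- function(ke, kt, filters) {
  list(kind = "conv", kernel = c(ke, kt), filters = filters,
       token = sprintf("Conv2D (%d %s %d) %s %d", ke, times_sign, kt,
                       times_sign, filters))
}
pool2_layer <- function(p1 = 2, p2 = 2) {
  list(kind = "pool", pool = c(p1, p2),
       token = sprintf("MaxPooling2D %d %s %d", p1, times_sign, p2))
}
# 3D tokens are printed as (time x width x height); internally the spatial
# axes are ordered (width, height, time), hence the reordering below.
conv3_layer <- function(kt, kw, kh, filters) {
  list(kind = "conv", kernel = c(kw, kh, kt), filters = filters,
       token = sprintf("Conv3D (%d %s %d %s %d) %s %d", kt, times_sign, kw,
                       times_sign, kh, times_sign, filters))
}
pool3_layer <- function(pt = 4, pw = 1, ph = 1) {
  list(kind = "pool", pool = c(pw, ph, pt),
       token = sprintf("MaxPooling3D %d %s %d %s %d", pt, times_sign, pw,
                       times_sign, ph))
}
dropout_layer <- function(rate = 0.5) {
  list(kind = "dropout", rate = rate, token = sprintf("Dropout %.1f", rate))
}
fc_layer <- function(units) {
  list(kind = "fc", units = units,
       token = sprintf("FC %d %s 1", units, times_sign))
}

arch_table_2d <- function() {
  tail2 <- list(dropout_layer(), fc_layer(128), dropout_layer(), fc_layer(2))
  list(
    "3Conv" = c(list(conv2_layer(5, 5, 32), conv2_layer(3, 3, 32),
                     pool2_layer(), conv2_layer(3, 3, 64)), tail2),
    "4Conv" = c(list(conv2_layer(5, 5, 32), conv2_layer(3, 3, 32),
                     pool2_layer(), conv2_layer(2, 2, 64),
                     conv2_layer(2, 2, 64)), tail2),
    "5Conv" = c(list(conv2_layer(5, 5, 32), conv2_layer(2, 2, 32),
                     conv2_layer(2, 2, 32), pool2_layer(),
                     conv2_layer(2, 2, 64), conv2_layer(2, 2, 64)), tail2),
    "6Conv" = c(list(conv2_layer(5, 5, 32), conv2_layer(2, 2, 32),
                     conv2_layer(2, 2, 32), pool2_layer(),
                     conv2_layer(2, 2, 64), conv2_layer(2, 2, 64),
                     conv2_layer(2, 1, 64)), tail2)
  )
}

arch_table_3d <- function() {
  tail2 <- list(dropout_layer(), fc_layer(128), dropout_layer(), fc_layer(2))
  list(
    "3Conv" = c(list(conv3_layer(9, 2, 3, 32), conv3_layer(3, 2, 3, 32),
                     pool3_layer(), conv3_layer(3, 1, 1, 64)), tail2),
    "4Conv" = c(list(conv3_layer(9, 2, 3, 32), conv3_layer(3, 2, 3, 32),
                     pool3_layer(), conv3_layer(3, 1, 1, 64),
                     conv3_layer(3, 1, 1, 64)), tail2),
    "5Conv" = c(list(conv3_layer(9, 2, 3, 32), conv3_layer(3, 2, 3, 32),
                     conv3_layer(3, 1, 1, 64), pool3_layer(),
                     conv3_layer(3, 1, 1, 64), conv3_layer(3, 1, 1, 64)),
                tail2),
    "6Conv" = c(list(conv3_layer(9, 2, 3, 32), conv3_layer(3, 2, 3, 32),
                     conv3_layer(3, 1, 1, 64), pool3_layer(),
                     conv3_layer(3, 1, 1, 64), conv3_layer(3, 1, 1, 64),
                     conv3_layer(3, 1, 1, 64)), tail2)
  )
}

#' Names of the available architectures
#'
#' @return Character vector `c("3Conv", "4Conv", "5Conv", "6Conv")`.
#' @export
cnn_architectures <- function() names(arch_table_2d())

#' Architecture specification
#'
#' Looks up one of the four model-family architectures in the requested
#' input mode.  2D models consume channels-x-time windows; 3D models consume
#' 5 x 3 scalp-grid stacks.  Convolutions use zero same-padding (required
#' for the deeper stacks to remain shape-feasible); pooling is valid.
#'
#' @param name One of `"3Conv"`, `"4Conv"`, `"5Conv"`, `"6Conv"`.
#' @param mode `"2D"` or `"3D"`.
#' @return A `cnn_arch_spec` with the ordered layer list and display tokens.
#' @export
architecture_spec <- function(name, mode = c("2D", "3D")) {
  mode <- match.arg(mode)
  tab <- if (mode == "2D") arch_table_2d() else arch_table_3d()
  if (!name %in% names(tab))
    stop("unknown architecture '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  structure(list(name = name, mode = mode, layers = tab[[name]]),
            class = "cnn_arch_spec")
}

#' Layer tokens of an architecture or built model
#'
#' The human-readable layer sequence, one token per layer, exactly as the
#' architecture tables print them.
#'
#' @param x A `cnn_arch_spec` or `cnn_model`.
#' @return Character vector of layer tokens.
#' @export
arch_tokens <- function(x) {
  spec <- if (inherits(x, "cnn_model")) x$spec else x
  stopifnot(inherits(spec, "cnn_arch_spec"))
  vapply(spec$layers, `[[`, character(1), "token")
}

#' @export
print.cnn_arch_spec <- function(x, ...) {
  cat(sprintf("<cnn_arch_spec> %s (%s input)\n", x$name, x$mode))
  cat(paste0("  ", arch_tokens(x), collapse = "\n"), "\n")
  invisible(x)
}
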