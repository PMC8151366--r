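#' Species richness of one unit in one latent-state draw
#'
#' @param z Binary species x unit matrix (one posterior draw of the latent
#'   presence states).
#' @param j Unit index.
#' @return Integer number of species present at unit `j`.
#' @export
unit_richness <- function(z, j) {
  z <- as.matrix(z)
  if (j < 1 || j > ncol(z)) stop_input("unit index out of range")
  sum(z[, j])
}

#' Posterior species-richness contrast between two survey conditions
#'
#' For each retained draw, unit-level richness (number of species whose
#' latent state is 1) is averaged over the units belonging to each condition
#' of a covariate pair, and the difference is taken; the contrast draws are
#' summarized by their mean and 95% credible interval. Conventions follow the
#' reference condition first: spring minus fall, enhancement minus none,
#' low-pesticide minus high-pesticide.
#'
#' @param post A fitted [fit_community_model()] posterior.
#' @param grouping One of `"season"`, `"enhancement"`, `"pesticide"`.
#' @return Object of class `richness_summary`: per-draw group means and
#'   contrast draws, posterior `mean`, `cri`, `excludes_zero`, and the group
#'   labels.
#' @export
richness_contrast <- function(post, grouping = c("season", "enhancement", "pesticide")) {
  grouping <- match.arg(grouping)
  u <- post$data$units
  groups <- switch(grouping,
    season = list(spring = which(u$season_fall == 0), fall = which(u$season_fall == 1)),
    enhancement = list(enhancement = which(u$enhancement == 1),
                       no_enhancement = which(u$enhancement == 0)),
    pesticide = list(low_pesticide = which(u$pesticide_high == 0),
                     high_pesticide = which(u$pesticide_high == 1))
  )
  if (any(lengths(groups) == 0L))
    stop_input("one condition group is empty for grouping '", grouping, "'")
  nd <- dim(post$z)[1]
  rich <- apply(post$z, c(1, 3), sum)           # draws x units
  g1 <- rowMeans(rich[, groups[[1]], drop = FALSE])
  g2 <- rowMeans(rich[, groups[[2]], drop = FALSE])
  contrast <- g1 - g2
  structure(list(
    grouping = grouping, labels = names(groups),
    group_draws = cbind(g1, g2), contrast_draws = contrast,
    mean = mean(contrast), cri = cri(contrast, 0.95),
    excludes_zero = prod(cri(contrast, 0.95)) > 0
  ), class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("<richness_summary> %s - %s = %.2f (95%% CRI: [%.2f, %.2f])%s\n",
              x$labels[1], x$labels[2], x$mean, x$cri[1], x$cri[2],
              if (x$excludes_zero) " *" else ""))
  invisible(x)
}

#' All three headline richness contrasts as a table
#'
#' @inheritParams richness_contrast
#' @return Data frame with one row per contrast (`contrast`, `mean`, `lo95`,
#'   `hi95`, `excludes_zero`).
#' @export
richness_contrast_table <- function(post) {
  rows <- lapply(c("season", "enhancement", "pesticide"), function(g) {
    rc <- richness_contrast(post, g)
    data.frame(contrast = paste(rc$labels[1], "-", rc$labels[2]),
               mean = rc$mean, lo95 = rc$cri[1], hi95 = rc$cri[2],
               excludes_zero = rc$excludes_zero,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
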