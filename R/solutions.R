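#' Define an ionic bathing solution
#'
#' Builds the ion totals used in dilution-potential calculations either from
#' a salt recipe (NaCl, KCl, MgCl2, CaCl2, all in mM) or from explicit Na/K/Cl
#' totals.  Chloride contributed by divalent salts counts twice; non-ionic
#' components (glucose, sucrose, HEPES) are osmotic ballast and are ignored.
#'
#' @param NaCl,KCl,MgCl2,CaCl2 salt concentrations in mM.
#' @param Na,K,Cl optional explicit ion totals (mM); when any is given, all
#'   three must be and the recipe arguments are ignored.
#' @param name optional label.
#' @return an `ion_solution`: list with `Na`, `K`, `Cl` (mM) and `name`.
#' @examples
#' ion_solution(NaCl = 140, KCl = 5, MgCl2 = 1, CaCl2 = 1)$Cl  # 149
#' @export
ion_solution <- function(NaCl = 0, KCl = 0, MgCl2 = 0, CaCl2 = 0,
                         Na = NULL, K = NULL, Cl = NULL, name = "") {
  explicit <- !is.null(Na) || !is.null(K) || !is.null(Cl)
  if (explicit) {
    if (is.null(Na) || is.null(K) || is.null(Cl))
      stop("give all of Na, K and Cl, or none")
  } else {
    stopifnot(NaCl >= 0, KCl >= 0, MgCl2 >= 0, CaCl2 >= 0)
    Na <- NaCl
    K <- KCl
    Cl <- NaCl + KCl + 2 * MgCl2 + 2 * CaCl2
  }
  stopifnot(Na >= 0, K >= 0, Cl >= 0)
  structure(list(Na = Na, K = K, Cl = Cl, name = name),
            class = "ion_solution")
}

#' Standard apical Ringer (solution A)
#'
#' 140 mM NaCl, 5 mM KCl, 1 mM MgCl2, 1 mM CaCl2 (plus 5 mM glucose and
#' 10 mM HEPES-NaOH pH 7.4, which do not enter the ionic bookkeeping).
#' @return an [ion_solution()].
#' @export
solution_a <- function() {
  ion_solution(NaCl = 140, KCl = 5, MgCl2 = 1, CaCl2 = 1, name = "A")
}

#' Half-NaCl basolateral Ringer (solution B)
#'
#' As [solution_a()] but with 70 mM NaCl, osmotically balanced by 130 mM
#' sucrose.  The apical/basolateral A-B pair produces the NaCl dilution
#' potential from which charge selectivity is read out.
#' @return an [ion_solution()].
#' @export
solution_b <- function() {
  ion_solution(NaCl = 70, KCl = 5, MgCl2 = 1, CaCl2 = 1, name = "B")
}

#' @export
print.ion_solution <- function(x, ...) {
  cat(sprintf("ion_solution %s: Na %.6g mM, K %.6g mM, Cl %.6g mM\n",
              if (nzchar(x$name)) x$name else "<unnamed>", x$Na, x$K, x$Cl))
  invisible(x)
}

same_solution <- function(a, b, tol = 1e-12) {
  abs(a$Na - b$Na) <= tol && abs(a$K - b$K) <= tol && abs(a$Cl - b$Cl) <= tol
}
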