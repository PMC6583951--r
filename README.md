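# cnfield

Two identical gray rings can look pink or orange depending on whether the
annuli around them alternate purple/lime or lime/purple. Psychophysicists
measure such color induction with *asymmetric matching*: an observer
adjusts a comparison patch on a neutral surround until it looks like the
test patch embedded in a patterned surround, and the *shift*
`c_match - c_test` quantifies the induction. Two opposing effects are at
work — chromatic assimilation (appearance drawn toward adjacent colors)
and simultaneous contrast (pushed toward the opponent of remote colors) —
and they act together.

`cnfield` implements a cortical model that unifies both effects and
predicts matching data. It is aimed at computational neuroscientists and
visual psychophysicists who want to simulate the model, emulate matching
experiments, and fit its parameters to shift data.

## The model

Color-tuned hypercolumns of V1 form a neural field `a(r, c, t)` over
cortical position `r` and opponent color `c`, evolving by a Wilson–Cowan
equation

    tau da/dt = -a + F(omega * a + H),      F(x) = 1/(1 + exp(-gamma x))

with feedforward drive `H(r, c) = mu_h exp(-|c - I(r)|^2 / 2 sigma_h^2)`
for a stimulus `I`, and a separable lateral kernel
`omega(r, c, r', c') = g(r - r') f(c, c')` where

    g(r)     = mu  exp(-|r|^2 /2 alpha^2)   - nu   exp(-|r|^2 /2 beta^2)     (Mexican hat, mu > nu)
    f(c, c') = mu_c exp(-|c - c'|^2/2 alpha_c^2) - nu_c exp(-|c + c'|^2/2 beta_c^2)

The second Gaussian of `f` is centered at the Hering opponent `-c`: nearby
neighbors of similar color excite (assimilation), remote neighbors excite
the opponent color (contrast). The *color sensation* at a point is the
steady-state activity profile of that hypercolumn over color space, and a
matching experiment is emulated as a projection,

    c_match = argmin_c || a_test - a_comp[c] ||_Linf,

searched on a candidate lattice with a SoftMin. Model parameters
`q = (mu_c, nu_c, alpha_c, beta_c, mu, nu, alpha, beta, mu_h, sigma_h,
gamma)` are fit to matching data by minimizing the sum of squared
prediction errors with a bounded derivative-free simplex. Four regressed
vectors (`q_MC`, `q_AZ`, `q_nonlin`, `q_HSL`) ship as fixtures.

## Worked example

Predict the shifts for the eight canonical striped patterns (p/p, l/l,
p/w, l/w, w/p, w/l, p/l, l/p; p = purple `c = 1.0`, l = lime `c = -0.84`,
w = white `c = -0.02`) with a neutral test stripe under the `q_MC`
parameters:

```r
library(cnfield)
tab <- ms_shift_experiment(named_params("q_MC"))
tab[, c("id", "c_test_1", "c_pred_1", "shift_1")]
```

```
  id c_test_1 c_pred_1  shift_1
1  0        0  0.01804  0.01804
2  1        0 -0.01927 -0.01927
3  2        0  0.01759  0.01759
4  3        0 -0.02069 -0.02069
5  4        0 -0.00387 -0.00387
6  5        0  0.00355  0.00355
7  6        0  0.02359  0.02359
8  7        0 -0.02486 -0.02486
```

Each row is one test pattern; `shift_1` is the predicted matching shift
along the S-cone opponent axis `c = s - 1`. The structure is the
experimental signature of synergy: purple-adjacent patterns shift positive
(toward purple), lime-adjacent negative, the uniform-surround patterns
(0, 1) and white-mixed patterns (2, 3) sit in between, and the two
two-color patterns p/l (6) and l/p (7) produce the largest shifts of
opposite sign — adjacent attraction and remote repulsion adding up.

The chromatic-disk analogue (`hsl_shift_experiment(named_params("q_HSL"))`)
emulates matching of 36 test colors inside a Yellow surround against a
Gray comparison surround and reproduces the "yellow pushes toward blue"
vector field of shifts.

A thin CLI wraps these functions for shell use
(`inst/cli/cnfield.R`, subcommands `simulate | match | fit | synth`), e.g.

```sh
Rscript inst/cli/cnfield.R match --config inst/extdata/configs/ms1d.yaml --out shifts.csv
```

Every run writes a `<out>.meta.json` sidecar with the materialized config
and solver diagnostics.

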