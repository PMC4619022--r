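# Recursion audit notes

Every dynamic program in this package is required to agree with the
exhaustive enumeration oracle (`enumerate_structures()` +
`count_neighbors()` + `energy_of_structure()`) on all small instances; the
test suite enforces this. Where commonly stated textbook-style formulations
of these recursions disagree with the oracle, the audited working form is
recorded here.

## Homopolymer model (Model A)

* Base cases: `E_0 = 0` and `Q_0 = 0`. (Some statements of these recursions
  set both to 1; the oracle check at n = 3 — two structures, one external
  pair, two directed MS2 moves — forces 0. With `E_0 = 1` the recursion for
  `E_n` yields `E_3 = 2` instead of 1, and with `Q_0 = 1` the move total at
  n = 3 becomes 3 instead of 2.)
* `Z_{-1} = 0`, `Z_n = 1` for `0 <= n <= theta + 1`.
* All summation upper bounds are written as `n - theta - 2` (pair-closing
  convolutions) or `n - theta - 1` (pair-to-end sums); with `theta = 1` these
  coincide with the familiar `n - 3` / `n - 2` bounds.
* The shift reservoirs for general theta decompose over the rightmost paired
  position of the `theta`-wide tail, exactly as the interval model's
  `ER'`/`G` functions do; the theta = 1 special case collapses to the
  two-term `E_{n-2} + sum_r E_r Z_{n-r-3}` form.

## Uniform interval model (Model B)

* The pair predicate `bp(i, j)` is false whenever `j - i <= theta`, so every
  printed-style summation bound (e.g. `k` running to `j`) is safe.
* `F` recursion, subcase `x > 0`: the carry term for "j unpaired and j not
  pairable with c" is required:
  `F[i,j,c,x] += (1 - bp(j,c)) * F[i,j-1,c,x]`.
  Without it the partition identity `sum_x F[i,j,c,x] = Z[i,j]` fails for
  every interval whose right end cannot pair with `c`.
* `ER'` tail loop runs `u = 1..theta` (not a hard-coded 3), as do the tail
  loops of `G`.

## Boltzmann interval model (Model C)

* Multiloop closing decomposition: with `ZM1` defined without a per-branch
  term and `ZM` adding `b` for every component it places, the closing line
  must carry `exp(-(a + 2b)/RT)` — one `b` for the closing pair and one for
  the last component, whose `ZM1` factor has none of its own. With
  `exp(-(a + b)/RT)` a k-component multiloop receives `a + b*k` instead of
  the affine `a + b*(k+1)`; the Boltzmann enumeration oracle catches this as
  a factor `exp(-b/RT)` on every multiloop-closed substructure.
* The restricted move taxonomy implied by the Q/QB/QM/QM1 recursions (and
  implemented by `count_neighbors(..., restricted = TRUE)`) is spelled out
  in the methods vignette; its non-obvious points are that boundary shifts
  of a multiloop-closing pair (e.g. `(i,j) -> (i+1,j)`) belong to the
  *inward* class and are therefore excluded, and that the left-pivot shift
  of a component is only counted for the loop's first component.
* Interior-loop bounds cap each side at `max_loop` unpaired nucleotides in
  the loop ranges while the energy function applies the joint cap; the two
  are consistent because the energy function returns `+Inf` (weight 0) for
  any loop exceeding the joint cap.
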