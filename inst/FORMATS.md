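# File formats

## Ratings CSV (canonical data interchange)

Long format, one observed score per row. Incomplete rating designs make the
ratee x item x rater array ragged, so the long format is canonical.

| column | type | meaning |
|--------|------|---------|
| ratee  | opaque id | the person being rated |
| item   | opaque id | checklist item / task; must match a Q-matrix row |
| rater  | opaque id | the rater giving the score |
| score  | 0 or 1 | dichotomous rating |

Ids are opaque strings mapped to dense indices internally (numeric-looking
ids sort numerically, otherwise lexically); the mapping is persisted in the
`ids` block of the results JSON. Duplicate (ratee, item, rater) triples and
non-binary scores are rejected with the offending line number.

## Truth sidecar CSV

`write_ratings()` on a simulated object also writes `<name>_truth.csv`:
column `ratee` then one 0/1 column per attribute (the generating profiles).

## Q-matrix CSV

Header row of attribute names, one row per item, 0/1 cells. Every row and
every column must contain at least one 1.

## Config YAML

Keys: `model` (standard|facets|hrm), `cdm` (saturated|dina), `design`
(complete|balanced|unbalanced|random), `iterations`, `burnin`, `thin`,
`chains`, `seed` (mandatory for simulation/replication; no default).

## Results JSON (`fit` verb / `write_fit_json()`)

- `model`, `cdm`
- `parameters`: list of `{name, eap, sd, rhat}` — item coefficients
  (`lambda0[j]`, `lambda1[j]`, `lambda2[j]` or `delta[j]`), rater parameters
  (`eta[r]` for facets; `phi[r]`, `psi[r]` for HRM when estimated), class
  weights (`pi[c]`)
- `mastery`: per ratee, posterior mastery probability per attribute
- `profiles`: per ratee, classified profile as a 0/1 string
- `ids`: the ratee/item/rater id maps

## Recovery report CSV (`replicate` verb / `report_table()`)

One row per generating parameter: `parameter`, `gen`, then
`<design>.<fit>.bias` / `<design>.<fit>.rmse` per condition; footer rows
`recovery.min/max/mean/sd` carry the whole-pattern profile recovery
statistics (percent) across replications in the `.bias` columns.
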