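Reported 2015 estimates for the WHO Eastern Mediterranean Region,
transcribed for use as arithmetic cross-check inputs:

- eamreg_2015_need_table.csv: per-country at-most/at-least symptom days
  (millions), decedents, non-decedents and total people in need of
  palliative care (thousands), by income group, with the reported Total row.
  Palestine appears as "No data" and contributes nothing to totals.
- eamreg_2015_workforce_table.csv: for Afghanistan, Morocco and Jordan:
  population, patients in need, encounter days per care level, home visits,
  absolute FTEs per staff category, and FTEs per 100,000 population.

These are transcribed reported values, not quantities computed by this
package. They feed only the normalization/aggregation cross-checks (e.g.
FTE-per-100,000 arithmetic, column summation); the reported per-country
estimates themselves depend on WHO Global Health Estimates extracts and
Lancet-Commission appendix coefficient tables that are not reprinted here,
so they are not reproduced from first principles.

Known internal inconsistencies of the source, carried verbatim:
- Afghanistan decedents: 95 thousand in the need table vs 93,373 in the
  workforce table.
- total_patients rows disagree slightly with decedents + nondecedents for
  Afghanistan (172,541 vs 170,812) and Jordan (22,339 vs 24,036).
- Morocco's total_home_visits equals Afghanistan's, a likely transcription
  artifact of the source.
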