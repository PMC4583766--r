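# Tiny SBML L3 fixture (written programmatically at test time) plus its
# sidecar dialect file carrying atom maps and the label input.

write_sbml_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("sbml-fixture-")
    dir.create(dir)
  }
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="mini">
    <listOfSpecies>
      <species id="S" initialConcentration="1" boundaryCondition="true"/>
      <species id="A" initialConcentration="0.5" boundaryCondition="false"/>
      <species id="B" initialConcentration="0.3" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="Vmax" value="2"/>
      <parameter id="Km" value="0.5"/>
      <parameter id="kv" value="3"/>
      <parameter id="Keq" value="4"/>
      <parameter id="kout" value="1.5"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="v1" reversible="false">
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><divide/>
              <apply><times/><ci>Vmax</ci><ci>S</ci></apply>
              <apply><plus/><ci>Km</ci><ci>S</ci></apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="v2" reversible="true">
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>kv</ci>
              <apply><minus/><ci>A</ci>
                <apply><divide/><ci>B</ci><ci>Keq</ci></apply>
              </apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="v3" reversible="false">
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>kout</ci><ci>B</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
  sidecar <- '
metabolites:
- {id: S, atoms: 2}
- {id: A, atoms: 2}
- {id: B, atoms: 2}
reactions:
- {id: v1, atoms: "S(ab) -> A(ab)"}
- {id: v2, atoms: "A(ab) -> B(ba)", keq: Keq}
- {id: v3, atoms: "B(ab) -> SINK(ab)"}
label_input:
  S: {"11": 1.0}
'
  sbml_path <- file.path(dir, "mini.xml")
  side_path <- file.path(dir, "mini-atoms.yml")
  writeLines(sbml, sbml_path)
  writeLines(sidecar, side_path)
  list(sbml = sbml_path, sidecar = side_path)
}
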