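<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="sbml_toy" fbc:strict="true">
    <listOfParameters>
      <parameter id="lb_ex" value="-10" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="big" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="glc" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="bio_m" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="prd" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="G_g4" fbc:label="g4"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_glc" reversible="true" fast="false" fbc:lowerFluxBound="lb_ex" fbc:upperFluxBound="zero">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="CNV" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="bio_m" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_g1"/>
              <fbc:geneProductRef fbc:geneProduct="G_g2"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_g3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="LEAK" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="prd" stoichiometry="0.5" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g4"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_prd" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="prd" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="BIO" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="bio_m" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj1">
      <fbc:objective fbc:id="obj1" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIO" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
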