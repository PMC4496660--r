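<?xml version="1.0"?>
<Ontology xmlns="http://www.w3.org/2002/07/owl#">
  <Declaration><Class IRI="#Acidity_Regulator"/></Declaration>
  <Declaration><Class IRI="#Anticaking_Agent"/></Declaration>
  <Declaration><Class IRI="#Antioxidant"/></Declaration>
  <Declaration><Class IRI="#Ascorbic_Acid"/></Declaration>
  <Declaration><Class IRI="#D-Isoascorbic_Acid"/></Declaration>
  <Declaration><NamedIndividual IRI="#Ascorbic_Acid"/></Declaration>
  <ClassAssertion><Class IRI="#Ascorbic_Acid"/><NamedIndividual IRI="#Ascorbic_Acid"/></ClassAssertion>
  <SubClassOf><Class IRI="#Ascorbic_Acid"/><Class IRI="#Antioxidant"/></SubClassOf>
  <SubClassOf><Class IRI="#Ascorbyl_Palmitate"/><Class IRI="#Ascorbic_Acid"/></SubClassOf>
  <SubClassOf><Class IRI="#D-Isoascorbic_Acid"/><Class IRI="#Ascorbic_Acid"/></SubClassOf>
  <SubClassOf><Class IRI="#Ester-C"/><Class IRI="#Ascorbic_Acid"/></SubClassOf>
  <ObjectPropertyAssertion><ObjectProperty IRI="#Has_Deficiency_Disease"/><NamedIndividual IRI="#Ascorbic_Acid"/><NamedIndividual IRI="#Scurvy"/></ObjectPropertyAssertion>
  <ObjectPropertyAssertion><ObjectProperty IRI="#Has_Overdose_Disease"/><NamedIndividual IRI="#Ascorbic_Acid"/><NamedIndividual IRI="#Vitamin_C_mega_dosage"/></ObjectPropertyAssertion>
  <ObjectPropertyAssertion><ObjectProperty IRI="#Has_Synonym"/><NamedIndividual IRI="#Ascorbic_Acid"/><NamedIndividual IRI="#E300"/></ObjectPropertyAssertion>
  <ObjectPropertyAssertion><ObjectProperty IRI="#Has_Synonym"/><NamedIndividual IRI="#Ascorbic_Acid"/><NamedIndividual IRI="#C_Vitamin"/></ObjectPropertyAssertion>
  <ObjectPropertyAssertion><ObjectProperty IRI="#Has_Solubility"/><NamedIndividual IRI="#Ascorbic_Acid"/><NamedIndividual IRI="#Water"/></ObjectPropertyAssertion>
</Ontology>
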