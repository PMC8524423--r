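#!/usr/bin/env Rscript
# Maintainer script: regenerates inst/extdata/fhir-r4-base.json, the vendored
# element metadata for the nineteen FHIR 4.0.1 resource types the compiler
# supports. The table deliberately covers all top-level elements of each type
# (plus the nested backbone paths profiles commonly constrain), not full
# snapshots. Element entries are (types, min, max). Elements common to every
# DomainResource are injected by the loader, not repeated here.
#
# Run from the package root:  Rscript tools/make-base-meta.R

el <- function(path, types, min = 0L, max = "*") {
  list(path = path, types = as.list(types), min = min, max = max)
}

res <- function(...) {
  xs <- list(...)
  out <- list()
  for (x in xs) out[[x$path]] <- list(types = x$types, min = x$min, max = x$max)
  out
}

CC <- "CodeableConcept"; RF <- "Reference"; BB <- "BackboneElement"
ID <- "Identifier"; AN <- "Annotation"; PD <- "Period"; DT <- "dateTime"

meta <- list(
  AllergyIntolerance = res(
    el("identifier", ID), el("clinicalStatus", CC, 0, "1"),
    el("verificationStatus", CC, 0, "1"), el("type", "code", 0, "1"),
    el("category", "code"), el("criticality", "code", 0, "1"),
    el("code", CC, 0, "1"), el("patient", RF, 1, "1"),
    el("encounter", RF, 0, "1"),
    el("onset[x]", c(DT, "Age", "Period", "Range", "string"), 0, "1"),
    el("recordedDate", DT, 0, "1"), el("recorder", RF, 0, "1"),
    el("asserter", RF, 0, "1"), el("lastOccurrence", DT, 0, "1"),
    el("note", AN), el("reaction", BB),
    el("reaction.substance", CC, 0, "1"),
    el("reaction.manifestation", CC, 1, "*"),
    el("reaction.severity", "code", 0, "1")
  ),
  Appointment = res(
    el("identifier", ID), el("status", "code", 1, "1"),
    el("cancelationReason", CC, 0, "1"), el("serviceCategory", CC),
    el("serviceType", CC), el("specialty", CC),
    el("appointmentType", CC, 0, "1"), el("reasonCode", CC),
    el("reasonReference", RF), el("priority", "unsignedInt", 0, "1"),
    el("description", "string", 0, "1"), el("supportingInformation", RF),
    el("start", "instant", 0, "1"), el("end", "instant", 0, "1"),
    el("minutesDuration", "positiveInt", 0, "1"), el("slot", RF),
    el("created", DT, 0, "1"), el("comment", "string", 0, "1"),
    el("patientInstruction", "string", 0, "1"), el("basedOn", RF),
    el("participant", BB, 1, "*"),
    el("participant.type", CC), el("participant.actor", RF, 0, "1"),
    el("participant.required", "code", 0, "1"),
    el("participant.status", "code", 1, "1"),
    el("requestedPeriod", PD)
  ),
  CarePlan = res(
    el("identifier", ID), el("instantiatesCanonical", "canonical"),
    el("instantiatesUri", "uri"), el("basedOn", RF), el("replaces", RF),
    el("partOf", RF), el("status", "code", 1, "1"),
    el("intent", "code", 1, "1"), el("category", CC),
    el("title", "string", 0, "1"), el("description", "string", 0, "1"),
    el("subject", RF, 1, "1"), el("encounter", RF, 0, "1"),
    el("period", PD, 0, "1"), el("created", DT, 0, "1"),
    el("author", RF, 0, "1"), el("contributor", RF), el("careTeam", RF),
    el("addresses", RF), el("supportingInfo", RF), el("goal", RF),
    el("activity", BB), el("activity.outcomeCodeableConcept", CC),
    el("activity.reference", RF, 0, "1"), el("activity.detail", BB, 0, "1"),
    el("activity.detail.code", CC, 0, "1"),
    el("activity.detail.status", "code", 1, "1"),
    el("note", AN)
  ),
  Communication = res(
    el("identifier", ID), el("instantiatesCanonical", "canonical"),
    el("instantiatesUri", "uri"), el("basedOn", RF), el("partOf", RF),
    el("inResponseTo", RF), el("status", "code", 1, "1"),
    el("statusReason", CC, 0, "1"), el("category", CC),
    el("priority", "code", 0, "1"), el("medium", CC),
    el("subject", RF, 0, "1"), el("topic", CC, 0, "1"), el("about", RF),
    el("encounter", RF, 0, "1"), el("sent", DT, 0, "1"),
    el("received", DT, 0, "1"), el("recipient", RF), el("sender", RF, 0, "1"),
    el("reasonCode", CC), el("reasonReference", RF),
    el("payload", BB),
    el("payload.content[x]", c("string", "Attachment", RF), 1, "1"),
    el("note", AN)
  ),
  Condition = res(
    el("identifier", ID), el("clinicalStatus", CC, 0, "1"),
    el("verificationStatus", CC, 0, "1"), el("category", CC),
    el("severity", CC, 0, "1"), el("code", CC, 0, "1"), el("bodySite", CC),
    el("subject", RF, 1, "1"), el("encounter", RF, 0, "1"),
    el("onset[x]", c(DT, "Age", "Period", "Range", "string"), 0, "1"),
    el("abatement[x]", c(DT, "Age", "Period", "Range", "string"), 0, "1"),
    el("recordedDate", DT, 0, "1"), el("recorder", RF, 0, "1"),
    el("asserter", RF, 0, "1"), el("stage", BB),
    el("stage.summary", CC, 0, "1"), el("stage.assessment", RF),
    el("stage.type", CC, 0, "1"), el("evidence", BB),
    el("evidence.code", CC), el("evidence.detail", RF), el("note", AN)
  ),
  Consent = res(
    el("identifier", ID), el("status", "code", 1, "1"),
    el("scope", CC, 1, "1"), el("category", CC, 1, "*"),
    el("patient", RF, 0, "1"), el("dateTime", DT, 0, "1"),
    el("performer", RF), el("organization", RF),
    el("source[x]", c("Attachment", RF), 0, "1"),
    el("policy", BB), el("policy.authority", "uri", 0, "1"),
    el("policy.uri", "uri", 0, "1"), el("policyRule", CC, 0, "1"),
    el("verification", BB), el("provision", BB, 0, "1"),
    el("provision.type", "code", 0, "1"), el("provision.period", PD, 0, "1")
  ),
  Coverage = res(
    el("identifier", ID), el("status", "code", 1, "1"),
    el("type", CC, 0, "1"), el("policyHolder", RF, 0, "1"),
    el("subscriber", RF, 0, "1"), el("subscriberId", "string", 0, "1"),
    el("beneficiary", RF, 1, "1"), el("dependent", "string", 0, "1"),
    el("relationship", CC, 0, "1"), el("period", PD, 0, "1"),
    el("payor", RF, 1, "*"), el("class", BB),
    el("class.type", CC, 1, "1"), el("class.value", "string", 1, "1"),
    el("class.name", "string", 0, "1"), el("order", "positiveInt", 0, "1"),
    el("network", "string", 0, "1"), el("subrogation", "boolean", 0, "1"),
    el("contract", RF)
  ),
  DeviceUseStatement = res(
    el("identifier", ID), el("basedOn", RF), el("status", "code", 1, "1"),
    el("subject", RF, 1, "1"), el("derivedFrom", RF),
    el("timing[x]", c("Timing", "Period", DT), 0, "1"),
    el("recordedOn", DT, 0, "1"), el("source", RF, 0, "1"),
    el("device", RF, 1, "1"), el("reasonCode", CC),
    el("reasonReference", RF), el("bodySite", CC, 0, "1"), el("note", AN)
  ),
  Encounter = res(
    el("identifier", ID), el("status", "code", 1, "1"),
    el("statusHistory", BB), el("class", "Coding", 1, "1"),
    el("classHistory", BB), el("type", CC), el("serviceType", CC, 0, "1"),
    el("priority", CC, 0, "1"), el("subject", RF, 0, "1"),
    el("episodeOfCare", RF), el("basedOn", RF), el("participant", BB),
    el("participant.type", CC), el("participant.period", PD, 0, "1"),
    el("participant.individual", RF, 0, "1"), el("appointment", RF),
    el("period", PD, 0, "1"), el("length", "Duration", 0, "1"),
    el("reasonCode", CC), el("reasonReference", RF), el("diagnosis", BB),
    el("diagnosis.condition", RF, 1, "1"), el("diagnosis.use", CC, 0, "1"),
    el("account", RF), el("hospitalization", BB, 0, "1"),
    el("location", BB), el("location.location", RF, 1, "1"),
    el("serviceProvider", RF, 0, "1"), el("partOf", RF, 0, "1")
  ),
  HealthcareService = res(
    el("identifier", ID), el("active", "boolean", 0, "1"),
    el("providedBy", RF, 0, "1"), el("category", CC), el("type", CC),
    el("specialty", CC), el("location", RF), el("name", "string", 0, "1"),
    el("comment", "string", 0, "1"), el("extraDetails", "markdown", 0, "1"),
    el("photo", "Attachment", 0, "1"), el("telecom", "ContactPoint"),
    el("coverageArea", RF), el("serviceProvisionCode", CC),
    el("eligibility", BB), el("eligibility.code", CC, 0, "1"),
    el("program", CC), el("characteristic", CC), el("communication", CC),
    el("referralMethod", CC), el("appointmentRequired", "boolean", 0, "1"),
    el("availableTime", BB), el("notAvailable", BB),
    el("availabilityExceptions", "string", 0, "1"), el("endpoint", RF)
  ),
  Medication = res(
    el("identifier", ID), el("code", CC, 0, "1"),
    el("status", "code", 0, "1"), el("manufacturer", RF, 0, "1"),
    el("form", CC, 0, "1"), el("amount", "Ratio", 0, "1"),
    el("ingredient", BB),
    el("ingredient.item[x]", c(CC, RF), 1, "1"),
    el("ingredient.isActive", "boolean", 0, "1"),
    el("ingredient.strength", "Ratio", 0, "1"),
    el("batch", BB, 0, "1"), el("batch.lotNumber", "string", 0, "1"),
    el("batch.expirationDate", DT, 0, "1")
  ),
  MedicationAdministration = res(
    el("identifier", ID), el("instantiates", "uri"), el("partOf", RF),
    el("status", "code", 1, "1"), el("statusReason", CC),
    el("category", CC, 0, "1"),
    el("medication[x]", c(CC, RF), 1, "1"),
    el("subject", RF, 1, "1"), el("context", RF, 0, "1"),
    el("supportingInformation", RF),
    el("effective[x]", c(DT, "Period"), 1, "1"),
    el("performer", BB), el("performer.function", CC, 0, "1"),
    el("performer.actor", RF, 1, "1"), el("reasonCode", CC),
    el("reasonReference", RF), el("request", RF, 0, "1"),
    el("device", RF), el("note", AN), el("dosage", BB, 0, "1"),
    el("dosage.route", CC, 0, "1"), el("dosage.dose", "Quantity", 0, "1"),
    el("eventHistory", RF)
  ),
  MedicationStatement = res(
    el("identifier", ID), el("basedOn", RF), el("partOf", RF),
    el("status", "code", 1, "1"), el("statusReason", CC),
    el("category", CC, 0, "1"),
    el("medication[x]", c(CC, RF), 1, "1"),
    el("subject", RF, 1, "1"), el("context", RF, 0, "1"),
    el("effective[x]", c(DT, "Period"), 0, "1"),
    el("dateAsserted", DT, 0, "1"), el("informationSource", RF, 0, "1"),
    el("derivedFrom", RF), el("reasonCode", CC), el("reasonReference", RF),
    el("note", AN), el("dosage", "Dosage")
  ),
  Observation = res(
    el("identifier", ID), el("basedOn", RF), el("partOf", RF),
    el("status", "code", 1, "1"), el("category", CC),
    el("code", CC, 1, "1"), el("subject", RF, 0, "1"), el("focus", RF),
    el("encounter", RF, 0, "1"),
    el("effective[x]", c(DT, "Period", "Timing", "instant"), 0, "1"),
    el("issued", "instant", 0, "1"), el("performer", RF),
    el("value[x]", c("Quantity", CC, "string", "boolean", "integer",
                     "Range", "Ratio", "SampledData", "time", DT, "Period"),
       0, "1"),
    el("dataAbsentReason", CC, 0, "1"), el("interpretation", CC),
    el("note", AN), el("bodySite", CC, 0, "1"), el("method", CC, 0, "1"),
    el("specimen", RF, 0, "1"), el("device", RF, 0, "1"),
    el("referenceRange", BB),
    el("referenceRange.low", "Quantity", 0, "1"),
    el("referenceRange.high", "Quantity", 0, "1"),
    el("hasMember", RF), el("derivedFrom", RF), el("component", BB),
    el("component.code", CC, 1, "1"),
    el("component.value[x]", c("Quantity", CC, "string", "boolean",
                               "integer", "Range", "Ratio", "SampledData",
                               "time", DT, "Period"), 0, "1"),
    el("component.dataAbsentReason", CC, 0, "1")
  ),
  Patient = res(
    el("identifier", ID), el("active", "boolean", 0, "1"),
    el("name", "HumanName"), el("telecom", "ContactPoint"),
    el("gender", "code", 0, "1"), el("birthDate", "date", 0, "1"),
    el("deceased[x]", c("boolean", DT), 0, "1"), el("address", "Address"),
    el("maritalStatus", CC, 0, "1"),
    el("multipleBirth[x]", c("boolean", "integer"), 0, "1"),
    el("photo", "Attachment"), el("contact", BB),
    el("contact.relationship", CC), el("contact.name", "HumanName", 0, "1"),
    el("contact.telecom", "ContactPoint"),
    el("contact.address", "Address", 0, "1"),
    el("contact.gender", "code", 0, "1"),
    el("communication", BB), el("communication.language", CC, 1, "1"),
    el("communication.preferred", "boolean", 0, "1"),
    el("generalPractitioner", RF), el("managingOrganization", RF, 0, "1"),
    el("link", BB), el("link.other", RF, 1, "1"),
    el("link.type", "code", 1, "1")
  ),
  Practitioner = res(
    el("identifier", ID), el("active", "boolean", 0, "1"),
    el("name", "HumanName"), el("telecom", "ContactPoint"),
    el("address", "Address"), el("gender", "code", 0, "1"),
    el("birthDate", "date", 0, "1"), el("photo", "Attachment"),
    el("qualification", BB),
    el("qualification.identifier", ID),
    el("qualification.code", CC, 1, "1"),
    el("qualification.period", PD, 0, "1"),
    el("qualification.issuer", RF, 0, "1"),
    el("communication", CC)
  ),
  Procedure = res(
    el("identifier", ID), el("instantiatesCanonical", "canonical"),
    el("instantiatesUri", "uri"), el("basedOn", RF), el("partOf", RF),
    el("status", "code", 1, "1"), el("statusReason", CC, 0, "1"),
    el("category", CC, 0, "1"), el("code", CC, 0, "1"),
    el("subject", RF, 1, "1"), el("encounter", RF, 0, "1"),
    el("performed[x]", c(DT, "Period", "string", "Age", "Range"), 0, "1"),
    el("recorder", RF, 0, "1"), el("asserter", RF, 0, "1"),
    el("performer", BB), el("performer.function", CC, 0, "1"),
    el("performer.actor", RF, 1, "1"), el("location", RF, 0, "1"),
    el("reasonCode", CC), el("reasonReference", RF), el("bodySite", CC),
    el("outcome", CC, 0, "1"), el("report", RF), el("complication", CC),
    el("complicationDetail", RF), el("followUp", CC), el("note", AN),
    el("focalDevice", BB), el("usedReference", RF), el("usedCode", CC)
  ),
  ServiceRequest = res(
    el("identifier", ID), el("instantiatesCanonical", "canonical"),
    el("instantiatesUri", "uri"), el("basedOn", RF), el("replaces", RF),
    el("requisition", ID, 0, "1"), el("status", "code", 1, "1"),
    el("intent", "code", 1, "1"), el("category", CC),
    el("priority", "code", 0, "1"), el("doNotPerform", "boolean", 0, "1"),
    el("code", CC, 0, "1"), el("orderDetail", CC),
    el("quantity[x]", c("Quantity", "Ratio", "Range"), 0, "1"),
    el("subject", RF, 1, "1"), el("encounter", RF, 0, "1"),
    el("occurrence[x]", c(DT, "Period", "Timing"), 0, "1"),
    el("asNeeded[x]", c("boolean", CC), 0, "1"),
    el("authoredOn", DT, 0, "1"), el("requester", RF, 0, "1"),
    el("performerType", CC, 0, "1"), el("performer", RF),
    el("locationCode", CC), el("locationReference", RF),
    el("reasonCode", CC), el("reasonReference", RF), el("insurance", RF),
    el("supportingInfo", RF), el("specimen", RF), el("bodySite", CC),
    el("note", AN), el("patientInstruction", "string", 0, "1"),
    el("relevantHistory", RF)
  ),
  Specimen = res(
    el("identifier", ID), el("accessionIdentifier", ID, 0, "1"),
    el("status", "code", 0, "1"), el("type", CC, 0, "1"),
    el("subject", RF, 0, "1"), el("receivedTime", DT, 0, "1"),
    el("parent", RF), el("request", RF), el("collection", BB, 0, "1"),
    el("collection.collector", RF, 0, "1"),
    el("collection.collected[x]", c(DT, "Period"), 0, "1"),
    el("collection.duration", "Duration", 0, "1"),
    el("collection.quantity", "Quantity", 0, "1"),
    el("collection.method", CC, 0, "1"),
    el("collection.bodySite", CC, 0, "1"),
    el("processing", BB), el("container", BB),
    el("condition", CC), el("note", AN)
  )
)

payload <- list(
  fhirVersion = "4.0.1",
  resources = lapply(names(meta), function(ty) {
    list(canonical = paste0("http://hl7.org/fhir/StructureDefinition/", ty),
         elements = meta[[ty]])
  })
)
names(payload$resources) <- names(meta)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null")
writeLines(json, "inst/extdata/fhir-r4-base.json")
cat(sprintf("wrote inst/extdata/fhir-r4-base.json (%d resource types)\n",
            length(meta)))
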